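combined_label,member_match,combined_atc5
sulfamethoxazole and trimethoprim,sulfamethoxazole,J01EE01
sulfamethoxazole and trimethoprim,trimethoprim,J01EE01
sulfamethoxazole and trimethoprim,co-trimoxazole,J01EE01
amoxicillin and enzyme inhibitors,amoxicillin and clavulanic acid,J01CR02
amoxicillin and enzyme inhibitors,clavulanic acid,J01CR02
piperacillin and enzyme inhibitors,piperacillin,J01CR05
piperacillin and enzyme inhibitors,tazobactam,J01CR05
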