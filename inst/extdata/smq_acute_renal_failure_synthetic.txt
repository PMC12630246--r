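# Synthetic stand-in for a narrow acute-renal-failure SMQ term list.
# One MedDRA-style Preferred Term per line; '#' starts a comment.
# This is NOT licensed MedDRA content.
Acute kidney injury
Renal failure
Anuria
Oliguria
Renal impairment
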