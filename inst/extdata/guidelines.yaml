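# Drinking-water guideline limits (ug/L) by standard, and chronic oral
# reference doses RfD (mg/kg/day) used by the non-carcinogenic risk cascade.
limits:
  WHO:
    arsenic: 10
    antimony: 20
    selenium: 40
rfd:
  arsenic: 0.0003
  antimony: 0.0004
  selenium: 0.005
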