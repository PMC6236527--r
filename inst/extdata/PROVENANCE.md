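# Packaged fixture provenance

`table2_overall.csv` and `table3_seasonal.csv` transcribe the published
per-well summary tables of the 2016 shallow-groundwater monitoring campaign
in Ibadan metropolis, southwestern Nigeria: 35 open dug wells (24
residential GW1-GW24, 5 commercial GW25-GW29, 4 industrial GW30-GW33, 2
agricultural GW34-GW35), each sampled monthly three times per season (dry:
January-March; wet: May-July) and analysed for arsenic, antimony and
selenium by ICP-OES. Concentrations are in ug/L. Zeros are below-detection
measurements recorded as zero and are included in all means, matching the
source tables' arithmetic.

Transcription normalizations (obvious typographical defects in the printed
tables, each forced by internal consistency of the tables themselves):

- GW32 arsenic overall range printed "(0.21.0)" -> 0 to 21.0.
- GW21 selenium overall range printed "16.0-64.0)" -> 16.0 to 64.0.
- GW29 selenium overall range printed "(8.0-51-0)" -> 8.0 to 51.0.
- GW32 dry-season selenium printed "0.026" with no SD -> 26.0 (SD left
  blank): the printed overall mean 16.2 for that well equals
  (6.33 + 26.07)/2, and every other well satisfies
  overall = (wet + dry)/2 within printing precision.

`guidelines.yaml` carries the WHO drinking-water limits and the reference
doses the study's risk cascade uses.
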