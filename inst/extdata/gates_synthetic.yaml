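# Synthetic placeholder gate coordinates for the R1/R2/R3 PI-uptake regions,
# calibrated to the package's own event generator. Published dotplots do not
# print numeric gate boundaries: replace these with instrument-specific
# values before analysing real data.
fsc_threshold: 80000
gates:
  - name: R1        # healthy, PI-negative
    channel: FL3
    low: 0
    high: 600
    space: linear
    priority: 1
  - name: R2        # intermediate PI uptake
    channel: FL3
    low: 600
    high: 8000
    space: linear
    priority: 2
  - name: R3        # damaged (heat-killed band)
    channel: FL3
    low: 8000
    high: .inf
    space: linear
    priority: 3
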