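# Default nitrate endmembers for coastal East Antarctic lake catchments.
# Units: per mil. Atmospheric values are annual means at a coastal station;
# biological delta-18O is the published nitrification-product value.
atmospheric:
  d18O: 92
  sigma_d18O: 0
  D17O: 32
  sigma_D17O: 0
biological:
  d18O: 0.6
  sigma_d18O: 0
  D17O: 0
  sigma_D17O: 0
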