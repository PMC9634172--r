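specimen: specimen_id
cell_id: cell_id
x: x_um
'y': y_um
area: nuclear_area_um2
units: um
intensities:
  CD4: CD4
  CD8: CD8
  FOXP3: FOXP3
  Ki67: Ki67
  PD1: PD1
  CK: CK
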