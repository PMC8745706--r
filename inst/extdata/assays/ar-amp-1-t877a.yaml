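assay_id: AR-Amp-1/T877A
targets:
- name: MT
  channel: CH1_FAM
  amplitude_level: 5000.0
  role: mutant
  chromosome: X
  alleles_per_normal_cell:
    male: 1
    female: 2
- name: WT
  channel: CH2_HEX
  amplitude_level: 3000.0
  role: wildtype
  chromosome: X
  alleles_per_normal_cell:
    male: 1
    female: 2
- name: RPP30
  channel: CH2_HEX
  amplitude_level: 6000.0
  role: reference
  chromosome: '10'
  alleles_per_normal_cell:
    male: 2
    female: 2
probe_metadata:
- target: MT
  forward_primer: CCCTACAGATTGCGAGAGAGC
  reverse_primer: GAAAGTCCACGCTCACCATGT
  primer_nM: 500.0
  probe: '[6FAM]ATCAGTTCGCTTTTGACCTG[BHQ1]'
  probe_nM: 250.0
- target: WT
  forward_primer: CCCTACAGATTGCGAGAGAGC
  reverse_primer: GAAAGTCCACGCTCACCATGT
  primer_nM: 500.0
  probe: '[HEX]ATCAGTTCACTTTTGACCTG[BHQ1]'
  probe_nM: 250.0
- target: RPP30
  forward_primer: GATTTGGACCTGCGAGCG
  reverse_primer: GCGGCTGTCTCCACAAGT
  primer_nM: 500.0
  probe: '[HEX]TCTGACCTGAAGGCTCTG[BHQ1]'
  probe_nM: 250.0
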