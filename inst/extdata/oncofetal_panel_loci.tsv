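mirna_id	locus
hsa-miR-1290	chr1−:18897078-18897096
hsa-miR-1343	chr11+:34941851-34941872
hsa-miR-301b	chr22+:21652990-21653011
hsa-miR-3170	chr13+:98208533-98208554
hsa-miR-323b	chr14+:101056233-101056255
hsa-miR-329	chr14+:101026797-101026819
hsa-miR-380	chr14+:101025021-101025042
hsa-miR-433	chr14+:100881897-100881918
hsa-miR-4787	chr3+:50675093-50675114
hsa-miR-543	chr14+:101032033-101032054
hsa-miR-5684	chr19+:12787132-12787151
hsa-miR-627	chr15-:42199630-42199651
hsa-miR-6516	chr17+:77089428-77089449
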