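# nuclide: cu64
# injected_mbq: 3.7
# decay_corrected: true
# arm: baseline
# Published group-mean biodistribution (%ID/g, n = 4 per timepoint) of
# Cu-64-PCTA-cetuximab in SNU-1066 HNSCC tumor-bearing mice. One row per
# organ x timepoint; each row is the printed group mean entered as a single
# observation, so per-animal scatter is not represented (SD column carries
# the printed SD for reference). Tissue masses were not published (mass_g
# empty).
organ	animal_id	time	time_unit	mass_g	pidg	sd_published
tumor	groupmean	2	h	NA	3.9	1.3
tumor	groupmean	24	h	NA	8.4	1.0
tumor	groupmean	48	h	NA	12.8	1.7
blood	groupmean	2	h	NA	30.8	4.7
blood	groupmean	24	h	NA	13.3	1.0
blood	groupmean	48	h	NA	11.7	1.9
muscle	groupmean	2	h	NA	1.3	0.1
muscle	groupmean	24	h	NA	2.5	0.2
muscle	groupmean	48	h	NA	2.5	0.4
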