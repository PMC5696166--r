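# nuclide: lu177
# injected_mbq: 3.7
# decay_corrected: true
# arm: baseline
# Published group-mean biodistribution (%ID/g, n = 4 per timepoint) of
# Lu-177-PCTA-cetuximab in SNU-1066 HNSCC tumor-bearing mice, 2 h to 14 d.
# One row per organ x timepoint; each row is the printed group mean entered
# as a single observation (SD column carries the printed SD for reference).
# Tissue masses were not published (mass_g empty).
organ	animal_id	time	time_unit	mass_g	pidg	sd_published
tumor	groupmean	2	h	NA	2.5	0.6
tumor	groupmean	1	d	NA	11.4	2.6
tumor	groupmean	3	d	NA	17.9	5.3
tumor	groupmean	5	d	NA	16.8	2.6
tumor	groupmean	7	d	NA	20.6	5.2
tumor	groupmean	14	d	NA	17.5	4.9
blood	groupmean	2	h	NA	29.0	3.6
blood	groupmean	1	d	NA	13.0	2.0
blood	groupmean	3	d	NA	8.9	2.1
blood	groupmean	5	d	NA	5.8	2.0
blood	groupmean	7	d	NA	3.8	1.3
blood	groupmean	14	d	NA	2.3	0.4
muscle	groupmean	2	h	NA	1.1	0.1
muscle	groupmean	1	d	NA	2.2	0.1
muscle	groupmean	3	d	NA	1.4	0.2
muscle	groupmean	5	d	NA	1.0	0.4
muscle	groupmean	7	d	NA	0.9	0.1
muscle	groupmean	14	d	NA	0.5	0.1
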