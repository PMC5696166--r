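# Biodistribution organ labels -> phantom organ names. Labels are matched
# after lower-casing and replacing spaces/hyphens with underscores.
# Extendable with a user file of the same layout (see organ_aliases()).
alias	organ
s.i.	small_intestine
si	small_intestine
small_intestine	small_intestine
l.i.	large_intestine
li	large_intestine
large_intestine	large_intestine
uli	upper_large_intestine
lli	lower_large_intestine
kidney	kidneys
lung	lungs
femur	bone
bone_marrow	red_marrow
marrow	red_marrow
bladder	urinary_bladder
heart_wall	heart
stomach_wall	stomach
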