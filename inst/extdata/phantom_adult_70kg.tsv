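# name: adult_70kg_reference
# body_mass_kg: 70
# Organ masses (g) of the hermaphroditic adult mathematical phantom
# (Cristy & Eckerman ORNL report series / MIRD Pamphlet geometry), the organ
# set used by organ-level internal dose codes, with the body mass taken as
# the nominal 70-kg standard adult. Fully overridable by a user file with
# the same layout.
organ	mass_g
adrenals	16.3
brain	1420
breasts	351
heart	316
kidneys	299
liver	1910
lungs	1000
muscle	28000
ovaries	8.71
pancreas	94.3
red_marrow	1120
skin	3010
small_intestine	677
spleen	183
stomach	158
testes	39.1
thymus	20.9
thyroid	20.7
upper_large_intestine	220
lower_large_intestine	160
large_intestine	380
urinary_bladder	47.6
uterus	79
blood	5500
bone	10000
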