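# Radionuclide decay constants used by the dose engine.
# half_life_h: physical half-life in hours.
# mean_np_kev: mean non-penetrating (beta + conversion/Auger electron) energy
#   emitted per decay, keV.
# photons: principal photon lines as energy_kev:yield pairs, ';'-separated
#   (carried for reporting; the default self-dose engine deposits electrons
#   only).
# Values from the ICRP Publication 107 / MIRD radionuclide decay-data
# compilations: Lu-177 T1/2 = 6.647 d with principal gammas 208.4 keV (10.4%)
# and 113.0 keV (6.2%); Cu-64 T1/2 = 12.701 h, beta- (38.5%, mean 190.7 keV)
# and beta+ (17.6%, mean 278.2 keV) branches, 511 keV annihilation photons.
name	half_life_h	mean_np_kev	photons
lu177	159.528	147.9	208.366:0.1038;112.95:0.0620
cu64	12.701	122.3	511.0:0.3520;1345.77:0.00475
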