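# Internal helpers exercised directly by the unit tests.
unit3 <- rodgate:::unit3
vec_angle <- rodgate:::vec_angle
cyl_radius <- rodgate:::cyl_radius
transform_segment <- rodgate:::transform_segment
segment_ends <- rodgate:::segment_ends
element_triad <- rodgate:::element_triad
spring_response <- rodgate:::spring_response
hinge_energy <- rodgate:::hinge_energy
hinge_response <- rodgate:::hinge_response
rot_exp <- rodgate:::rot_exp
rot_log <- rodgate:::rot_log
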