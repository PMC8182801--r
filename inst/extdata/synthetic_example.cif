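# Synthetic example CIF (generated for documentation; not a real structure).
# Only cell-level tags are meaningful to this package.
data_synthetic_monoclinic_100K
_cell_length_a      11.6400(20)
_cell_length_b      12.8930(30)
_cell_length_c      15.0210(40)
_cell_angle_alpha   90
_cell_angle_beta    101.350(20)
_cell_angle_gamma   90
_diffrn_ambient_temperature 100(2)
_refine_ls_R_factor_gt 0.0380
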