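# Simplified Ramachandran region polygons (degrees) used by
# ramachandran_fractions(). Deliberately coarse, documented basins rather
# than a statistical validator: "favored" covers the core beta/polyproline-II
# basin (including its psi ~ -180 tail, which wraps around the map edge) and
# the core right-handed alpha basin; "allowed" additionally covers generously
# extended versions of both plus the left-handed alpha basin. Everything else
# is classified unfavorable. Vertices are listed in order; polygons are
# closed implicitly. A (phi, psi) pair on a boundary counts as inside.
class	polygon	phi	psi
favored	beta	-180	80
favored	beta	-45	80
favored	beta	-45	180
favored	beta	-180	180
favored	beta_tail	-180	-180
favored	beta_tail	-45	-180
favored	beta_tail	-45	-160
favored	beta_tail	-180	-160
favored	alpha_r	-120	-80
favored	alpha_r	-30	-80
favored	alpha_r	-30	0
favored	alpha_r	-120	0
allowed	beta_ext	-180	60
allowed	beta_ext	-20	60
allowed	beta_ext	-20	180
allowed	beta_ext	-180	180
allowed	beta_ext_tail	-180	-180
allowed	beta_ext_tail	-20	-180
allowed	beta_ext_tail	-20	-140
allowed	beta_ext_tail	-180	-140
allowed	alpha_r_ext	-160	-100
allowed	alpha_r_ext	-20	-100
allowed	alpha_r_ext	-20	30
allowed	alpha_r_ext	-160	30
allowed	alpha_l	20	-30
allowed	alpha_l	100	-30
allowed	alpha_l	100	90
allowed	alpha_l	20	90
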