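# Ideal side-chain internal-coordinate tables (heavy atoms, CB included).
# Auto-derived from CCD ideal residue geometry; do not edit numbers by hand.
# Columns: atom, frame a/b/c, chi index (0 = fixed torsion), bond length (A),
# bond angle (deg), torsion offset (deg): torsion = chi_k + offset.
.sidechain_geom <- list(
  A = list(
    list("CB","C","N","CA",0L,1.5294,109.465,-119.999)
  ),
  R = list(
    list("CB","C","N","CA",0L,1.5363,111.550,-123.561),
    list("CG","N","CA","CB",1L,1.5371,114.536,0.000),
    list("CD","CA","CB","CG",2L,1.5273,112.417,0.000),
    list("NE","CB","CG","CD",3L,1.4435,111.016,0.000),
    list("CZ","CG","CD","NE",4L,1.4058,123.005,0.000),
    list("NH1","CD","NE","CZ",0L,1.3906,120.996,179.986),
    list("NH2","CD","NE","CZ",0L,1.3912,119.815,-0.012)
  ),
  N = list(
    list("CB","C","N","CA",0L,1.5309,109.454,-119.996),
    list("CG","N","CA","CB",1L,1.5066,109.484,0.000),
    list("OD1","CA","CB","CG",2L,1.2133,119.974,0.000),
    list("ND2","CA","CB","CG",2L,1.3476,120.012,-179.926)
  ),
  D = list(
    list("CB","C","N","CA",0L,1.5301,109.480,-120.011),
    list("CG","N","CA","CB",1L,1.5075,109.463,0.000),
    list("OD1","CA","CB","CG",2L,1.2080,119.959,0.000),
    list("OD2","CA","CB","CG",2L,1.3415,119.999,-179.936)
  ),
  C = list(
    list("CB","C","N","CA",0L,1.5285,109.496,-120.014),
    list("SG","N","CA","CB",1L,1.8141,109.498,0.000)
  ),
  Q = list(
    list("CB","C","N","CA",0L,1.5288,109.459,-120.066),
    list("CG","N","CA","CB",1L,1.5284,109.534,0.000),
    list("CD","CA","CB","CG",2L,1.5066,109.543,0.000),
    list("OE1","CB","CG","CD",3L,1.2122,119.937,0.000),
    list("NE2","CB","CG","CD",3L,1.3471,120.093,-179.957)
  ),
  E = list(
    list("CB","C","N","CA",0L,1.5302,109.482,-119.956),
    list("CG","N","CA","CB",1L,1.5306,109.402,0.000),
    list("CD","CA","CB","CG",2L,1.5076,109.430,0.000),
    list("OE1","CB","CG","CD",3L,1.2084,120.003,0.000),
    list("OE2","CB","CG","CD",3L,1.3425,119.998,-179.937)
  ),
  H = list(
    list("CB","C","N","CA",0L,1.5337,111.125,-122.779),
    list("CG","N","CA","CB",1L,1.5100,112.979,0.000),
    list("ND1","CA","CB","CG",2L,1.3513,120.329,0.000),
    list("CD2","CA","CB","CG",2L,1.3376,129.928,179.846),
    list("CE1","CB","CG","ND1",0L,1.3369,107.862,179.905),
    list("NE2","CG","ND1","CE1",0L,1.3370,107.617,-0.043)
  ),
  I = list(
    list("CB","C","N","CA",0L,1.5288,109.430,-120.073),
    list("CG1","N","CA","CB",1L,1.5294,109.547,0.000),
    list("CG2","N","CA","CB",1L,1.5303,109.458,-119.972),
    list("CD1","CA","CB","CG1",2L,1.5288,109.547,0.000)
  ),
  L = list(
    list("CB","C","N","CA",0L,1.5286,109.416,-119.973),
    list("CG","N","CA","CB",1L,1.5303,109.495,0.000),
    list("CD1","CA","CB","CG",2L,1.5300,109.500,0.000),
    list("CD2","CA","CB","CG",2L,1.5285,109.501,120.092)
  ),
  K = list(
    list("CB","C","N","CA",0L,1.5300,109.453,-119.967),
    list("CG","N","CA","CB",1L,1.5307,109.418,0.000),
    list("CD","CA","CB","CG",2L,1.5308,109.441,0.000),
    list("CE","CB","CG","CD",3L,1.5291,109.465,0.000),
    list("NZ","CG","CD","CE",4L,1.4694,109.500,0.000)
  ),
  M = list(
    list("CB","C","N","CA",0L,1.5294,109.427,-120.037),
    list("CG","N","CA","CB",1L,1.5284,109.545,0.000),
    list("SD","CA","CB","CG",2L,1.8137,109.506,0.000),
    list("CE","CB","CG","SD",3L,1.8135,100.034,0.000)
  ),
  F = list(
    list("CB","C","N","CA",0L,1.5289,109.474,-120.094),
    list("CG","N","CA","CB",1L,1.5052,109.517,0.000),
    list("CD1","CA","CB","CG",2L,1.3817,120.058,0.000),
    list("CD2","CA","CB","CG",2L,1.3832,120.005,179.757),
    list("CE1","CB","CG","CD1",0L,1.3820,120.029,179.994),
    list("CE2","CB","CG","CD2",0L,1.3819,119.977,179.839),
    list("CZ","CG","CD1","CE1",0L,1.3806,120.047,-0.048)
  ),
  P = list(
    list("CB","C","N","CA",0L,1.5434,104.722,-118.841),
    list("CG","N","CA","CB",1L,1.5426,105.059,0.000),
    list("CD","CA","CB","CG",2L,1.5437,105.063,0.000)
  ),
  S = list(
    list("CB","C","N","CA",0L,1.5287,109.471,-120.020),
    list("OG","N","CA","CB",1L,1.4283,109.512,0.000)
  ),
  T = list(
    list("CB","C","N","CA",0L,1.5290,109.411,-120.000),
    list("OG1","N","CA","CB",1L,1.4280,109.505,0.000),
    list("CG2","N","CA","CB",1L,1.5301,109.525,-120.031)
  ),
  W = list(
    list("CB","C","N","CA",0L,1.5286,109.523,-120.026),
    list("CG","N","CA","CB",1L,1.5067,109.442,0.000),
    list("CD1","CA","CB","CG",2L,1.3426,126.496,0.000),
    list("CD2","CA","CB","CG",2L,1.4639,126.512,179.622),
    list("NE1","CB","CG","CD1",0L,1.3686,109.932,179.944),
    list("CE2","CB","CG","CD2",0L,1.4068,106.076,179.958),
    list("CE3","CB","CG","CD2",0L,1.3961,134.047,0.784),
    list("CZ2","CG","CD2","CE2",0L,1.3906,119.346,-179.825),
    list("CZ3","CG","CD2","CE3",0L,1.3659,119.795,179.639),
    list("CH2","CD2","CE2","CZ2",0L,1.3773,119.806,0.221)
  ),
  Y = list(
    list("CB","C","N","CA",0L,1.5287,109.470,-120.041),
    list("CG","N","CA","CB",1L,1.5062,109.497,0.000),
    list("CD1","CA","CB","CG",2L,1.3823,119.947,0.000),
    list("CD2","CA","CB","CG",2L,1.3830,119.943,179.692),
    list("CE1","CB","CG","CD1",0L,1.3810,120.073,-179.976),
    list("CE2","CB","CG","CD2",0L,1.3809,120.020,179.775),
    list("CZ","CG","CD1","CE1",0L,1.3867,119.978,-0.102),
    list("OH","CD1","CE1","CZ",0L,1.3582,120.130,-179.966)
  ),
  V = list(
    list("CB","C","N","CA",0L,1.5287,109.445,-120.004),
    list("CG1","N","CA","CB",1L,1.5299,109.509,0.000),
    list("CG2","N","CA","CB",1L,1.5292,109.490,120.026)
  )
)

# number of chi dihedrals per amino acid (Gly has no side chain)
.n_chi <- c(A = 0L, C = 1L, D = 2L, E = 3L, F = 2L, G = 0L, H = 2L, I = 2L, K = 4L, L = 2L, M = 3L, N = 2L, P = 2L, Q = 3L, R = 4L, S = 1L, T = 1L, V = 1L, W = 2L, Y = 2L)
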