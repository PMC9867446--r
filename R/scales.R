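# Physicochemical lookup tables.
#
# Average (not monoisotopic) residue masses in Da; protein mass adds one
# water. Kyte-Doolittle hydropathy values. Bjellqvist pKa set as used by
# ExPASy Compute pI: side chains D/E/C/Y/H/K/R plus free termini, with
# residue-specific N-terminal pKa corrections.

AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_AVG <- 18.01524

KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Bjellqvist pKa values (ExPASy Compute pI/Mw set)
PKA_SIDE <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
PKA_CTERM <- 3.55
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                          T = 6.82, V = 7.44, E = 7.7)

nterm_pka <- function(first_residue) {
  if (first_residue %in% names(PKA_NTERM_BY_RESIDUE))
    PKA_NTERM_BY_RESIDUE[[first_residue]]
  else PKA_NTERM_DEFAULT
}
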