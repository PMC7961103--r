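# Atomic and isotopic constants used by the mass engine.
#
# Monoisotopic masses (Da) follow the AME2020 atomic-mass evaluation;
# natural isotopic abundances follow the IUPAC representative values.
# These are the only mass constants in the package: every theoretical
# m/z is derived from this table.

# Monoisotopic masses of the isotopes the package models. "13C" and "D"
# are addressed as distinct symbols so that label substitution is pure
# bookkeeping on the formula, never a mass correction.
ISOTOPE_MASS <- c(
  "H"   = 1.00782503207,
  "D"   = 2.01410177785,
  "C"   = 12.0,
  "13C" = 13.00335483507,
  "N"   = 14.00307400443,
  "O"   = 15.99491461957,
  "P"   = 30.97376199842,
  "Na"  = 22.98976928199,
  "K"   = 38.96370648642
)

ELECTRON_MASS <- 0.000548579909

# Mass added by a singly charged cationic adduct: atom mass minus one
# electron. The lock-mass value printed for sodiated dipalmitoyl PC
# (756.551374) confirms the electron-subtraction convention.
ADDUCT_DELTA <- c(
  "H"  = ISOTOPE_MASS[["H"]] - ELECTRON_MASS,
  "Na" = ISOTOPE_MASS[["Na"]] - ELECTRON_MASS,
  "K"  = ISOTOPE_MASS[["K"]] - ELECTRON_MASS
)

# Natural-abundance isotope patterns per element, as (mass shift in
# nominal Da, probability). Monoisotopic elements are omitted. Sites
# already substituted with 13C or D are isotopically pure by definition.
NATURAL_ABUNDANCE <- list(
  "C" = list(shift = c(0L, 1L), prob = c(0.9893, 0.0107)),
  "H" = list(shift = c(0L, 1L), prob = c(0.999885, 0.000115)),
  "N" = list(shift = c(0L, 1L), prob = c(0.99636, 0.00364)),
  "O" = list(shift = c(0L, 1L, 2L), prob = c(0.99757, 0.00038, 0.00205))
)

# Mean nominal-mass spacing used to place aggregated isotopologue peaks
# on the m/z axis (the 13C-12C mass difference dominates CHNOP lipids).
C13_C12_DELTA <- ISOTOPE_MASS[["13C"]] - ISOTOPE_MASS[["C"]]
D_H_DELTA <- ISOTOPE_MASS[["D"]] - ISOTOPE_MASS[["H"]]
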