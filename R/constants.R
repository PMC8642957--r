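# Alphabets and physicochemical tables used by the descriptor code.
#
# The three property scales are the classical triple used by pseudo amino
# acid composition (hydrophobicity, hydrophilicity, side-chain mass); the
# CTD tables are the standard seven 3-class partitions of the 20 residues
# (hydrophobicity, normalized van der Waals volume, polarity, polarizability,
# charge, secondary structure, solvent accessibility).  The same definitions
# are shipped as TSV files under inst/extdata/ so they can be audited
# without reading source; a unit test asserts the two copies agree.

DNA_BASES <- c("A", "C", "G", "T")
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIG <- c("B", "Z", "X", "U", "O") # treated as maskable unknowns
RNA_AMBIG <- c("N")

# Hydrophobicity (Tanford), hydrophilicity (Hopp-Woods), side-chain mass.
AA_SCALES <- local({
  h1 <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
          H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
          H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
          P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
          W = -3.4, Y = -2.3)
  m  <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
          K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
          T = 45, V = 43, W = 130, Y = 107)
  rbind(hydrophobicity = h1[AA_ORDER],
        hydrophilicity = h2[AA_ORDER],
        side_chain_mass = m[AA_ORDER])
})

# Standardized (zero mean, unit sd across the 20 residues) versions used by
# the correlation-type descriptors (QSO, PAAC, Moreau-Broto).
AA_SCALES_Z <- t(apply(AA_SCALES, 1, function(v) (v - mean(v)) / sd(v)))

# CTD: seven properties, each partitioning the 20 residues into 3 classes.
CTD_GROUPS <- list(
  hydrophobicity = c(polar = "RKEDQN", neutral = "GASTPHY",
                     hydrophobic = "CLVIMFW"),
  vdw_volume = c(small = "GASTPDC", medium = "NVEQIL", large = "MHKFRYW"),
  polarity = c(low = "LIFWCMVY", medium = "PATGS", high = "HQRKNED"),
  polarizability = c(low = "GASDT", medium = "CPNVEQIL", high = "KMHFRYW"),
  charge = c(positive = "KR", neutral = "ANCQGHILMFPSTWYV", negative = "DE"),
  secondary_structure = c(helix = "EALMQKRH", strand = "VIYCWFT",
                          coil = "GNPSD"),
  solvent_accessibility = c(buried = "ALFCGIVW", exposed = "RKQEND",
                            intermediate = "MSPTHY")
)

# Conjoint-triad grouping: 7 physicochemical classes of the 20 residues.
CONJOINT_GROUPS <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")

# residue -> group index lookup for one partition given as strings
.group_lookup <- function(groups) {
  g <- integer(0)
  for (i in seq_along(groups)) {
    letters_i <- strsplit(groups[[i]], "")[[1]]
    g[letters_i] <- i
  }
  g[AA_ORDER]
}

CTD_LOOKUP <- lapply(CTD_GROUPS, .group_lookup)
CONJOINT_LOOKUP <- .group_lookup(CONJOINT_GROUPS)
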