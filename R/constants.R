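# Internal constant tables: residue masses, ionizable-group pK values,
# codon usage for the synthetic generator.

# Average (not monoisotopic) residue masses in Da, as used by ExPASy
# ProtParam.  A peptide's MW is the sum of residue masses plus one water.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist pK set (the set behind ExPASy Compute pI/MW).  The N-terminal
# pK depends on the first residue; side-chain pKs are residue-wise.
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70)
PK_NTERM_DEFAULT <- 7.50
PK_CTERM <- 3.55
PK_SIDE_POS <- c(K = 10.00, R = 12.00, H = 5.98)
PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)

# Default essential amino-acid set (histidine included; configurable in
# physchem()).
ESSENTIAL_AA_DEFAULT <- c("H", "I", "K", "L", "M", "F", "T", "W", "V")

# Canonical heptapeptide repeat unit tiling gamma-gliadin domain II.
HEPTAPEPTIDE_MOTIF <- "PQQPFPQ"

# B-cell 7-mer recognized by CD patients' B-cell antigen receptors.
BCELL_MOTIF <- "QPQQPFP"

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons the synthetic generator uses per residue.  Deliberately restricted:
# glutamine outside the poly-Q tract is encoded CAG-only and glutamate/leucine
# avoid GAA/CTA, so that single-base CAA mutants never occur outside the
# planted tract and the tract boundary is recoverable from the nucleotides.
# Further exclusions keep start codons out of unintended frames and strands:
# no codon ends in A or AT (so no spanning ATG/CAT), none is CAT, and TG-
# starting codons are confined to planted cysteines/tryptophan.
GEN_CODONS <- list(
  A = c("GCT", "GCC"), R = c("CGT", "CGC"), N = c("AAC"),
  D = c("GAT", "GAC"), C = c("TGT", "TGC"), E = c("GAG"),
  Q = c("CAG"), G = c("GGT", "GGC"), H = c("CAC"),
  I = c("ATT", "ATC"), L = c("CTT", "CTG", "CTC"), K = c("AAG"),
  M = c("ATG"), F = c("TTT", "TTC"), P = c("CCT", "CCC"),
  S = c("TCT", "TCC", "AGT"), T = c("ACT", "ACC"), W = c("TGG"),
  Y = c("TAC"), V = c("GTT", "GTC")
)

# Poly-Q tract codons: the canonical glutamine codon and its accepted
# single-base interruptions (each one substitution away from CAA).
POLYQ_CANONICAL <- "CAA"
POLYQ_INTERRUPTIONS <- c(CAG = "Q", GAA = "E", CTA = "L")
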