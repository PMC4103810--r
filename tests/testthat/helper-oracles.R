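# Shared fixtures and independent oracles for the test suite.

default_cal <- function() fp_calibration(0.0470, 0.1587, 0.70)

# Published peptide mimic sequences (12/16-mers) and motif-only entries used
# by the motif scanner tests; flanked variants embed each motif in a neutral
# glycine/serine context.
peptide_seqs <- list(
  PL    = "SAVLQKKITDYFHPKK",
  p21   = "RRQTSMTDFYHS",
  p66   = "NRQVSITGFFQR",
  Abl   = "PGQRSISLRYEG",
  Mcl1  = "GVQRNHETAFQG",
  p85a  = "TLQYLLKHFFKL",
  Akt   = "HRFFAGIVWQHV")

reported_predicted_motifs <- list(
  DNA_PK = "QYFMEQFY",
  Ku70   = "YFVALVPQ",
  MPG    = "YFCMNISSQ",
  NEK11  = "QLLLGVDY",
  PLCg   = "QEHLADHE",
  JAK3   = "QNPLGPDY",
  SBK1   = "QLGLALDF",
  PI3K   = "QYLLKHFF",
  Akt    = "FFAGIVWQ")

embed_motif <- function(motif, flank = "GSGSGS") paste0(flank, motif, flank)

write_motif_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}

# brute-force regular-expression motif oracle (overlapping matches via
# lookahead); counts forward + reverse hits of a pattern on one sequence
regex_hit_count <- function(seq, pattern) {
  cls <- function(p) paste0("[", paste(p, collapse = ""), "]")
  fwd <- paste0("(?=", paste(vapply(pattern$positions, cls, ""), collapse = ""), ")")
  rev_pat <- paste0("(?=", paste(vapply(rev(pattern$positions), cls, ""),
                                 collapse = ""), ")")
  cnt <- function(p) {
    m <- gregexpr(p, seq, perl = TRUE)[[1]]
    sum(m > 0)
  }
  cnt(fwd) + cnt(rev_pat)
}

# quaternion-method rigid superposition RMSD (independent of the Kabsch SVD
# route): minimum RMSD is sqrt((GA + GB - 2*lambda_max)/n) with lambda_max
# the largest eigenvalue of the 4x4 key matrix of the correlation.
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  Rm <- crossprod(B, A)
  S <- matrix(0, 4, 4)
  S[1, 1] <- Rm[1, 1] + Rm[2, 2] + Rm[3, 3]
  S[1, 2] <- S[2, 1] <- Rm[2, 3] - Rm[3, 2]
  S[1, 3] <- S[3, 1] <- Rm[3, 1] - Rm[1, 3]
  S[1, 4] <- S[4, 1] <- Rm[1, 2] - Rm[2, 1]
  S[2, 2] <- Rm[1, 1] - Rm[2, 2] - Rm[3, 3]
  S[2, 3] <- S[3, 2] <- Rm[1, 2] + Rm[2, 1]
  S[2, 4] <- S[4, 2] <- Rm[1, 3] + Rm[3, 1]
  S[3, 3] <- -Rm[1, 1] + Rm[2, 2] - Rm[3, 3]
  S[3, 4] <- S[4, 3] <- Rm[2, 3] + Rm[3, 2]
  S[4, 4] <- -Rm[1, 1] - Rm[2, 2] + Rm[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random valid equilibrium system spanning 1e-12..1e-3 M
rand_system <- function() {
  list(R_T = 10^stats::runif(1, -12, -3), L_ST = 10^stats::runif(1, -12, -3),
       L_T = 10^stats::runif(1, -12, -3), K_d1 = 10^stats::runif(1, -12, -3),
       K_d2 = 10^stats::runif(1, -12, -3))
}
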