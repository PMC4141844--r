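# Independent brute-force oracles and text fixtures built in code. These
# deliberately avoid the package's internal helpers: each oracle is a plain
# re-evaluation of the defining formula.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(AAS, len, replace = TRUE), collapse = "")
}

# 20 x n_index AAindex value matrix with amino-acid rows and index columns
aaindex_P <- function(aai) {
  m <- t(as.matrix(aai[, AAS]))
  rownames(m) <- AAS
  colnames(m) <- aai$index_id
  m
}

# O(n^2) pair-counting AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# plug-in MI in bits from a plain contingency table
oracle_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  total <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) {
      total <- total + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
    }
  }
  unname(total)
}

# equal-frequency terciles, ties by value then index (mirrors the stated
# discretization contract, written independently)
oracle_terciles <- function(x) {
  if (length(unique(x)) == 1) return(rep(1L, length(x)))
  ord <- order(x, seq_along(x))
  r <- integer(length(x)); r[ord] <- seq_along(x)
  as.integer(ceiling(3 * r / length(x)))
}

# exhaustive greedy mRMR (difference criterion) for small tables
oracle_mrmr <- function(mat, y, k) {
  D <- apply(mat, 2, oracle_terciles)
  rel <- apply(D, 2, oracle_mi, b = y)
  selected <- integer(0)
  for (round in seq_len(k)) {
    best <- -Inf; pick <- NA
    for (j in seq_len(ncol(mat))) {
      if (j %in% selected) next
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(g) oracle_mi(D[, j], D[, g]),
                    numeric(1)))
      }
      crit <- rel[j] - red
      if (crit > best + 1e-12) { best <- crit; pick <- j }
    }
    selected <- c(selected, pick)
  }
  colnames(mat)[selected]
}

# ---- descriptor-formula oracles -------------------------------------------

oracle_autocorr <- function(chars, scale, maxlag = 30) {
  n <- length(chars)
  ps <- (scale - mean(scale)) / sd(scale)
  xs <- ps[chars]; x <- scale[chars]
  xb <- mean(x)
  nmb <- moran <- geary <- numeric(maxlag)
  for (d in seq_len(maxlag)) {
    if (n <= d) next
    s1 <- 0; s2 <- 0; s3 <- 0
    for (i in seq_len(n - d)) {
      s1 <- s1 + xs[i] * xs[i + d]
      s2 <- s2 + (x[i] - xb) * (x[i + d] - xb)
      s3 <- s3 + (x[i] - x[i + d])^2
    }
    nmb[d] <- s1 / (n - d)
    den_m <- sum((x - xb)^2) / n
    if (den_m > 0) moran[d] <- (s2 / (n - d)) / den_m
    den_g <- sum((x - xb)^2) / (n - 1)
    if (den_g > 0) geary[d] <- (s3 / (2 * (n - d))) / den_g
  }
  list(nmb = nmb, moran = moran, geary = geary)
}

oracle_qso_tau <- function(chars, dm, maxlag = 30) {
  n <- length(chars)
  tau <- numeric(maxlag)
  for (d in seq_len(maxlag)) {
    if (n <= d) next
    for (i in seq_len(n - d)) {
      tau[d] <- tau[d] + dm[chars[i], chars[i + d]]^2
    }
  }
  tau
}

oracle_apaac <- function(chars, h1raw, h2raw, lambda = 30, w = 0.05) {
  n <- length(chars)
  std <- function(p) (p - mean(p)) / sd(p)
  h1 <- std(h1raw)[chars]; h2 <- std(h2raw)[chars]
  tau <- numeric(2 * lambda)
  for (j in seq_len(min(lambda, n - 1))) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(n - j)) {
      s1 <- s1 + h1[i] * h1[i + j]
      s2 <- s2 + h2[i] * h2[i + j]
    }
    tau[2 * j - 1] <- s1 / (n - j)
    tau[2 * j] <- s2 / (n - j)
  }
  f <- table(factor(chars, levels = AAS)) / n
  denom <- sum(f) + w * sum(abs(tau))
  c(as.numeric(f) / denom, w * tau / denom)
}

oracle_ctd_distribution <- function(chars, classes) {
  # classes: named class index per AA; returns 5 values per class 1..3
  cls <- classes[chars]
  n <- length(cls)
  out <- c()
  for (g in 1:3) {
    pos <- unname(which(cls == g))
    if (length(pos) == 0) { out <- c(out, rep(0, 5)); next }
    ks <- c(1, ceiling(c(0.25, 0.5, 0.75, 1) * length(pos)))
    out <- c(out, 100 * pos[ks] / n)
  }
  out
}

oracle_pi_grid <- function(sequence, resolution = 1e-3) {
  counts <- table(factor(strsplit(sequence, "")[[1]], levels = AAS))
  pka_pos <- c(nt = 8.6, K = 10.8, R = 12.5, H = 6.5)
  n_pos <- c(1, counts[["K"]], counts[["R"]], counts[["H"]])
  pka_neg <- c(ct = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  n_neg <- c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])
  grid <- seq(0, 14, by = resolution)
  q <- vapply(grid, function(ph) {
    sum(n_pos / (1 + 10^(ph - pka_pos))) -
      sum(n_neg / (1 + 10^(pka_neg - ph)))
  }, numeric(1))
  grid[which.min(abs(q))]
}

# ---- fixture builders ------------------------------------------------------

write_aaindex_fixture <- function(entries, path = tempfile(fileext = ".txt")) {
  # entries: named list index_id -> 20 values in AAindex I-block order
  # (A R N D C Q E G H I / L K M F P S T W Y V); NA written as "NA"
  lines <- c()
  for (id in names(entries)) {
    v <- entries[[id]]
    fmt <- function(x) ifelse(is.na(x), "NA", format(x))
    lines <- c(lines,
               paste("H", id),
               paste("D synthetic fixture entry", id),
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste0("   ", paste(fmt(v[1:10]), collapse = "   ")),
               paste0("   ", paste(fmt(v[11:20]), collapse = "   ")),
               "//")
  }
  writeLines(lines, path)
  path
}

write_fasta_fixture <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_status_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

make_status_row <- function(target, trial, status, date,
                            method = "X-ray",
                            stop_condition = "current status: work stopped") {
  tibble::tibble(target_id = target, trial_id = trial, status = status,
                 stop_date = date, method = method,
                 stop_condition = stop_condition)
}
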