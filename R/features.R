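# The 2,924-feature candidate encoder. Three AAindex blocks (whole-sequence,
# exposed-residue and buried-residue property means; 3 x 544), ten
# PROFEAT-style descriptor blocks (1,060), and 232 sequence/structure
# summary features. Block layout and feature ids are fixed by
# feature_registry(); encode_features() concatenates the blocks in registry
# order and is a pure function of (sequence, annotation, parameters).

#' Autocorrelation descriptor parameters
#'
#' @param properties Character vector of 3 AAindex ids (one hydrophobicity,
#'   one flexibility, one polarizability scale by default) used by the
#'   Moreau-Broto/Moran/Geary autocorrelations and the total-property
#'   descriptors.
#' @param maxlag Maximum sequence lag (default 30; 3 properties x 30 lags
#'   give the 90 features of each autocorrelation family).
#' @return A list of class `autocorr_params`.
#' @export
autocorr_params <- function(properties = DEFAULT_AUTOCORR_PROPERTIES,
                            maxlag = 30L) {
  stopifnot(length(properties) == 3L, maxlag >= 1L)
  if (is.null(names(properties))) {
    names(properties) <- c("p1", "p2", "p3")
  }
  structure(list(properties = properties, maxlag = as.integer(maxlag)),
            class = "autocorr_params")
}

#' Quasi-sequence-order parameters
#'
#' @param maxlag Maximum coupling lag (default 30).
#' @param weight Weight of the sequence-order terms (default 0.1).
#' @param matrices Named list of two 20x20 zero-diagonal distance matrices
#'   (defaults: the package physicochemical distance and the Grantham
#'   matrix). Two matrices x (30 coupling + 50 descriptors) = 160 features.
#' @return A list of class `qso_params`.
#' @export
qso_params <- function(maxlag = 30L, weight = 0.1,
                       matrices = list(pd = physico_distance_matrix(),
                                       gr = grantham_matrix())) {
  stopifnot(length(matrices) == 2L, !is.null(names(matrices)))
  structure(list(maxlag = as.integer(maxlag), weight = weight,
                 matrices = matrices),
            class = "qso_params")
}

#' Amphiphilic pseudo-amino-acid composition parameters
#'
#' @param lambda Number of correlation tiers (default 30; 20 + 2 x 30 = 80
#'   features).
#' @param weight Weight of the correlation terms (default 0.05).
#' @param hydrophobicity,hydrophilicity Named 20-value scales (defaults:
#'   Kyte-Doolittle and Hopp-Woods), standardized internally.
#' @return A list of class `apaac_params`.
#' @export
apaac_params <- function(lambda = 30L, weight = 0.05,
                         hydrophobicity = KD_HYDROPATHY,
                         hydrophilicity = HW_HYDROPHILICITY) {
  structure(list(lambda = as.integer(lambda), weight = weight,
                 hydrophobicity = hydrophobicity[AA_ALPHABET],
                 hydrophilicity = hydrophilicity[AA_ALPHABET]),
            class = "apaac_params")
}

# standardize a 20-value scale over the amino-acid alphabet
standardize_scale <- function(p) (p - mean(p)) / stats::sd(p)

# ---- registry --------------------------------------------------------------

registry_env <- new.env(parent = emptyenv())

#' The fixed feature registry
#'
#' Ordered catalogue of all 2,924 candidate features: block id, feature id
#' and position. AAindex blocks are 3 x 544, the PROFEAT-style blocks sum
#' to 1,060 (dipeptide 400; Moreau-Broto/Moran/Geary 90 each; CTD
#' 21+21+105; QSO 160; APAAC 80; total-property 3) and the remaining
#' sequence/structure blocks sum to 232, so that removing the AAindex
#' blocks leaves 2924 - 3 x 544 = 1292 features.
#'
#' @param aaindex AAindex table defining the 544 index ids (default: the
#'   bundled snapshot).
#' @return A tibble with columns `position`, `block`, `feature_id`.
#' @export
feature_registry <- function(aaindex = aaindex_table()) {
  default <- missing(aaindex)
  if (default && !is.null(registry_env$registry)) return(registry_env$registry)
  ids <- aaindex$index_id
  five <- attr(five_class_alphabet(), "classes")
  ten <- attr(functional_group_alphabet(), "classes")
  props <- names(DEFAULT_AUTOCORR_PROPERTIES)
  ctd <- names(ctd_partitions())
  qso_mats <- c("pd", "gr")
  states <- c("H", "E", "C")

  blocks <- list(
    aaindex_seq     = paste0("aaseq_", ids),
    aaindex_exposed = paste0("aaexp_", ids),
    aaindex_buried  = paste0("aabur_", ids),
    dipeptide = paste0("dipep_", rep(AA_ALPHABET, each = 20),
                       rep(AA_ALPHABET, 20)),
    nmbroto = paste0("nmb_", rep(props, each = 30), "_d", rep(1:30, 3)),
    moran   = paste0("moran_", rep(props, each = 30), "_d", rep(1:30, 3)),
    geary   = paste0("geary_", rep(props, each = 30), "_d", rep(1:30, 3)),
    ctd_c = paste0("ctdc_", rep(ctd, each = 3), "_g", rep(1:3, 7)),
    ctd_t = paste0("ctdt_", rep(ctd, each = 3), "_",
                   rep(c("g12", "g13", "g23"), 7)),
    ctd_d = paste0("ctdd_", rep(ctd, each = 15), "_g",
                   rep(rep(1:3, each = 5), 7), "_",
                   rep(c("first", "q25", "q50", "q75", "q100"), 21)),
    qso = c(paste0("qso_", rep(qso_mats, each = 30), "_tau", rep(1:30, 2)),
            unlist(lapply(qso_mats, function(m) {
              paste0("qso_", m, "_x", c(AA_ALPHABET, paste0("d", 1:30)))
            }))),
    apaac = c(paste0("apaac_", AA_ALPHABET), paste0("apaac_tau", 1:60)),
    taap = paste0("taap_", props),
    seqglobal = c("sg_length", "sg_log_length", "sg_pi", "sg_mean_mass",
                  "sg_mean_hydropathy", "sg_net_charge_per_res",
                  "sg_charge_balance", "sg_aromatic_frac", "sg_sulfur_frac",
                  "sg_cys_parity"),
    aa_comp = paste0("comp_", AA_ALPHABET),
    five_class_comp = paste0("comp5_", five),
    functional_group_comp = paste0("comp10_", ten),
    grouped_dipeptide = paste0("gdipep_", rep(seq_len(5), each = 5),
                               rep(seq_len(5), 5)),
    grouped_tripeptide = paste0("gtripep_",
                                rep(1:3, each = 9),
                                rep(rep(1:3, each = 3), 3),
                                rep(1:3, 9)),
    exposure = c("exp_frac",
                 paste0("expfreq_", AA_ALPHABET),
                 paste0("burfreq_", AA_ALPHABET),
                 paste0("expfreq5_", five), paste0("burfreq5_", five),
                 paste0("erun_ge", c(1, 2, 4, 8, 16)), "erun_max",
                 "erun_mean",
                 paste0("brun_ge", c(1, 2, 4, 8, 16)), "brun_max",
                 "brun_mean"),
    ss = c(paste0("ssfrac_", states),
           paste0("ss_", rep(states, each = 3), "_",
                  rep(c("meanseg", "maxseg", "nseg"), 3)),
           paste0("ss_", rep(states, each = 3), "_run_ge",
                  rep(c(1, 4, 8), 3)),
           paste0("ss_", rep(states, each = 5), "_",
                  rep(names(SS_AA_CLASSES), 3)),
           "ss_total_segs"),
    disorder = c("dis_frac", "dis_nseg", "dis_meanseg", "dis_maxseg",
                 paste0("dis_run_ge", c(4, 8, 16, 32)),
                 paste0("dis_ss_", states), "dis_nterm20", "dis_cterm20"),
    cross = c(paste0("disfreq5_", five),
              paste0("expss_", states), paste0("burss_", states),
              "dis_exp", "dis_bur",
              "exp_his", "bur_glu", "exp_glu", "bur_his",
              paste0("sshydro_", states))
  )
  reg <- tibble::tibble(
    block = rep(names(blocks), lengths(blocks)),
    feature_id = unlist(blocks, use.names = FALSE)
  )
  reg <- tibble::add_column(reg, position = seq_len(nrow(reg)), .before = 1L)
  stopifnot(nrow(reg) == 2924L, !anyDuplicated(reg$feature_id))
  if (default) registry_env$registry <- reg
  reg
}

# ---- individual encoders ---------------------------------------------------

count_kmers <- function(codes, k, n_classes) {
  # frequency vector over all ordered k-mers of a class-coded sequence
  n <- length(codes)
  out <- numeric(n_classes^k)
  if (n < k) return(out)
  idx <- codes[seq_len(n - k + 1L)]
  for (j in seq_len(k - 1L)) {
    idx <- (idx - 1L) * n_classes + codes[(1L + j):(n - k + 1L + j)]
  }
  tab <- tabulate(idx, nbins = n_classes^k)
  tab / (n - k + 1L)
}

#' Amino-acid and grouped compositions
#'
#' 87 features: 20 amino-acid fractions, 5 five-class fractions, 10
#' functional-group fractions, 25 grouped dipeptide fractions (five-class
#' alphabet) and 27 grouped tripeptide fractions (three-class alphabet).
#' Each sub-block sums to 1 (or 0 when the sequence is too short for the
#' k-mer to be defined).
#'
#' @param sequence A single amino-acid sequence string.
#' @return Named numeric vector of length 87.
#' @export
encode_compositions <- function(sequence) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  counts <- aa_counts(chars)
  five <- five_class_alphabet()
  ten <- functional_group_alphabet()
  three <- three_class_alphabet()
  comp20 <- counts / n
  comp5 <- tabulate(five[chars], 5L) / n
  comp10 <- tabulate(ten[chars], 10L) / n
  gdipep <- count_kmers(unname(five[chars]), 2L, 5L)
  gtripep <- count_kmers(unname(three[chars]), 3L, 3L)
  reg <- feature_registry()
  out <- c(comp20, comp5, comp10, gdipep, gtripep)
  names(out) <- reg$feature_id[reg$block %in%
    c("aa_comp", "five_class_comp", "functional_group_comp",
      "grouped_dipeptide", "grouped_tripeptide")]
  out
}

#' AAindex property means over the sequence and exposure classes
#'
#' For each of the 544 AAindex scales: the mean property over all residues
#' (`aaseq_*`), over predicted exposed residues (`aaexp_*`) and over
#' predicted buried residues (`aabur_*`). When an exposure class is empty
#' the corresponding block falls back to the whole-sequence mean.
#'
#' @param sequence Amino-acid sequence string.
#' @param exposure Exposure track string over {E,B} of the same length.
#' @param aaindex AAindex table (default: bundled snapshot).
#' @return Named numeric vector of length `3 * nrow(aaindex)`.
#' @export
encode_aaindex_blocks <- function(sequence, exposure,
                                  aaindex = aaindex_table()) {
  if (is.null(exposure) || is.na(exposure)) {
    stop("exposure track is required for the AAindex blocks", call. = FALSE)
  }
  chars <- seq_to_chars(sequence)
  expo <- seq_to_chars(exposure)
  stopifnot(length(expo) == length(chars))
  P <- aaindex_matrix(aaindex) # 20 x 544
  mean_block <- function(mask) {
    if (!any(mask)) return(NULL)
    cnt <- aa_counts(chars[mask])
    as.vector(crossprod(P, cnt)) / sum(cnt)
  }
  seq_mean <- mean_block(rep(TRUE, length(chars)))
  exp_mean <- mean_block(expo == "E")
  bur_mean <- mean_block(expo == "B")
  if (is.null(exp_mean)) exp_mean <- seq_mean
  if (is.null(bur_mean)) bur_mean <- seq_mean
  ids <- aaindex$index_id
  stats::setNames(c(seq_mean, exp_mean, bur_mean),
                  c(paste0("aaseq_", ids), paste0("aaexp_", ids),
                    paste0("aabur_", ids)))
}

#' Dipeptide composition
#'
#' The 400 ordered amino-acid pair frequencies `n_ab / (N - 1)` in fixed
#' row-major order over [AA_ALPHABET]; sums to 1 for sequences of length
#' at least 2.
#'
#' @param sequence Amino-acid sequence string.
#' @return Named numeric vector of length 400.
#' @export
encode_dipeptide <- function(sequence) {
  chars <- seq_to_chars(sequence)
  codes <- match(chars, AA_ALPHABET)
  if (length(chars) < 2L) {
    warning("sequence shorter than 2 residues: dipeptide block is all zero")
    out <- numeric(400L)
  } else {
    out <- count_kmers(codes, 2L, 20L)
  }
  names(out) <- paste0("dipep_", rep(AA_ALPHABET, each = 20),
                       rep(AA_ALPHABET, 20))
  out
}

#' Sequence autocorrelation descriptors
#'
#' Normalized Moreau-Broto, Moran and Geary autocorrelations of three
#' AAindex property scales at lags 1..30 (90 features per family).
#' Moreau-Broto uses the scale standardized over the 20 amino acids
#' (`AC(d) = mean of P'_i P'_{i+d}`); Moran and Geary use the raw scale
#' with the sequence mean. Lags not supported by the sequence length, and
#' zero-variance sequences for Moran/Geary, yield 0.
#'
#' @param sequence Amino-acid sequence string.
#' @param params An [autocorr_params()] list.
#' @param aaindex AAindex table resolving the property ids.
#' @return Named numeric vector of length 270 (Moreau-Broto, Moran, Geary).
#' @export
encode_autocorrelation <- function(sequence, params = autocorr_params(),
                                   aaindex = aaindex_table()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  maxlag <- params$maxlag
  P <- aaindex_matrix(aaindex)
  nmb <- moran <- geary <- NULL
  for (prop in params$properties) {
    scale <- P[, prop]
    xs <- standardize_scale(scale)[chars]
    x <- scale[chars]
    xb <- mean(x)
    dev <- x - xb
    ss_tot <- sum(dev^2)
    a_nmb <- a_moran <- a_geary <- numeric(maxlag)
    for (d in seq_len(maxlag)) {
      if (n > d) {
        i <- seq_len(n - d)
        a_nmb[d] <- sum(xs[i] * xs[i + d]) / (n - d)
        if (ss_tot > 0) {
          a_moran[d] <- (sum(dev[i] * dev[i + d]) / (n - d)) / (ss_tot / n)
          if (n > 1L) {
            a_geary[d] <- (sum((x[i] - x[i + d])^2) / (2 * (n - d))) /
              (ss_tot / (n - 1L))
          }
        }
      }
    }
    nmb <- c(nmb, a_nmb); moran <- c(moran, a_moran); geary <- c(geary, a_geary)
  }
  props <- names(params$properties)
  tag <- paste0(rep(props, each = maxlag), "_d", rep(seq_len(maxlag), 3))
  stats::setNames(c(nmb, moran, geary),
                  c(paste0("nmb_", tag), paste0("moran_", tag),
                    paste0("geary_", tag)))
}

#' Composition/transition/distribution descriptors
#'
#' For each of the seven three-class physicochemical partitions: the three
#' class fractions (composition, 21 features), the three unordered
#' class-pair transition frequencies `(n_rs + n_sr) / (N - 1)` (21), and
#' the distribution of each class (105): the 1-based position, scaled by
#' 100/N, of the first occurrence and of the `ceil(q * n_class)`-th
#' occurrence for q in {0.25, 0.5, 0.75, 1}. Absent classes give five
#' zeros.
#'
#' @param sequence Amino-acid sequence string.
#' @param partitions Seven-property partition list from [ctd_partitions()].
#' @return Named numeric vector of length 147.
#' @export
encode_ctd <- function(sequence, partitions = ctd_partitions()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  comp <- trans <- dist <- NULL
  for (pname in names(partitions)) {
    cls <- partitions[[pname]][chars]
    comp <- c(comp, tabulate(cls, 3L) / n)
    tr <- numeric(3L)
    if (n >= 2L) {
      a <- cls[-n]; b <- cls[-1L]
      pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
      tr <- vapply(pairs, function(p) {
        sum((a == p[1L] & b == p[2L]) | (a == p[2L] & b == p[1L])) / (n - 1L)
      }, numeric(1))
    }
    trans <- c(trans, tr)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos) == 0L) {
        dist <- c(dist, numeric(5L))
      } else {
        ks <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * length(pos)))
        dist <- c(dist, 100 * pos[ks] / n)
      }
    }
  }
  reg <- feature_registry()
  stats::setNames(c(comp, trans, dist),
                  reg$feature_id[reg$block %in% c("ctd_c", "ctd_t", "ctd_d")])
}

#' Quasi-sequence-order descriptors
#'
#' Sequence-order coupling numbers `tau_d = sum_i dist(s_i, s_{i+d})^2` for
#' d = 1..30 under each of two amino-acid distance matrices (60 features),
#' plus, per matrix, the 50 normalized descriptors
#' `X_a = f_a / (sum f + w sum tau)` for the 20 amino acids and
#' `X_{20+d} = w tau_d / (sum f + w sum tau)` (100 features). Lags at or
#' beyond the sequence length give `tau_d = 0`.
#'
#' @param sequence Amino-acid sequence string.
#' @param params A [qso_params()] list.
#' @return Named numeric vector of length 160.
#' @export
encode_qso <- function(sequence, params = qso_params()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  f <- aa_counts(chars) / n
  taus <- list(); descs <- list()
  for (m in names(params$matrices)) {
    dm <- params$matrices[[m]]
    tau <- numeric(params$maxlag)
    for (d in seq_len(params$maxlag)) {
      if (n > d) {
        i <- seq_len(n - d)
        tau[d] <- sum(dm[cbind(chars[i], chars[i + d])]^2)
      }
    }
    denom <- sum(f) + params$weight * sum(tau)
    descs[[m]] <- c(f / denom, params$weight * tau / denom)
    taus[[m]] <- tau
  }
  out <- c(unlist(taus, use.names = FALSE), unlist(descs, use.names = FALSE))
  mats <- names(params$matrices)
  names(out) <- c(
    paste0("qso_", rep(mats, each = params$maxlag), "_tau",
           rep(seq_len(params$maxlag), 2)),
    unlist(lapply(mats, function(m) {
      paste0("qso_", m, "_x", c(AA_ALPHABET, paste0("d", seq_len(params$maxlag))))
    }))
  )
  out
}

#' Amphiphilic pseudo-amino-acid composition
#'
#' 20 composition features plus 2*lambda amphiphilic correlation features
#' built from alternating hydrophobicity/hydrophilicity sequence
#' correlations `tau_{2j-1} = mean of H1'_i H1'_{i+j}`,
#' `tau_{2j} = mean of H2'_i H2'_{i+j}` (scales standardized over the 20
#' amino acids). The shared denominator is `sum f + w * sum |tau|`, so all
#' 80 features sum to 1 when every tau is non-negative. Sequences shorter
#' than lambda + 1 zero-pad the missing tiers.
#'
#' @param sequence Amino-acid sequence string.
#' @param params An [apaac_params()] list.
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
encode_apaac <- function(sequence, params = apaac_params()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  h1 <- standardize_scale(params$hydrophobicity)[chars]
  h2 <- standardize_scale(params$hydrophilicity)[chars]
  lambda <- params$lambda
  tau <- numeric(2L * lambda)
  for (j in seq_len(min(lambda, n - 1L))) {
    i <- seq_len(n - j)
    tau[2L * j - 1L] <- sum(h1[i] * h1[i + j]) / (n - j)
    tau[2L * j] <- sum(h2[i] * h2[i + j]) / (n - j)
  }
  f <- aa_counts(chars) / n
  denom <- sum(f) + params$weight * sum(abs(tau))
  out <- c(f / denom, params$weight * tau / denom)
  names(out) <- c(paste0("apaac_", AA_ALPHABET),
                  paste0("apaac_tau", seq_len(2L * lambda)))
  out
}

#' Total amino-acid properties
#'
#' The sequence-summed value of each of the three autocorrelation property
#' scales divided by N, i.e. the mean property per residue. Invariant under
#' sequence concatenation with itself.
#'
#' @param sequence Amino-acid sequence string.
#' @param params An [autocorr_params()] list naming the scales.
#' @param aaindex AAindex table resolving the property ids.
#' @return Named numeric vector of length 3.
#' @export
encode_taap <- function(sequence, params = autocorr_params(),
                        aaindex = aaindex_table()) {
  chars <- seq_to_chars(sequence)
  P <- aaindex_matrix(aaindex)
  vals <- vapply(params$properties, function(p) mean(P[chars, p]), numeric(1))
  stats::setNames(vals, paste0("taap_", names(params$properties)))
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge over the ionizable
#' side chains (D, E, C, Y, H, K, R) and the termini crosses zero, found by
#' bisection on [0, 14]. The net charge is strictly decreasing in pH so the
#' root is unique.
#'
#' @param sequence Amino-acid sequence string.
#' @param pka pKa table (list with `nterm`, `cterm`, `positive`,
#'   `negative`), default [PKA_TABLE].
#' @param tol Bisection tolerance in pH units (default 1e-4).
#' @return The isoelectric point (pH units).
#' @export
compute_pi <- function(sequence, pka = PKA_TABLE, tol = 1e-4) {
  counts <- aa_counts(seq_to_chars(sequence))
  charge <- function(ph) net_charge_at(ph, counts, pka)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

net_charge_at <- function(ph, counts, pka = PKA_TABLE) {
  pos_pka <- c(pka$nterm, pka$positive)
  pos_n <- c(1, counts[names(pka$positive)])
  neg_pka <- c(pka$cterm, pka$negative)
  neg_n <- c(1, counts[names(pka$negative)])
  sum(pos_n / (1 + 10^(ph - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - ph)))
}

# ---- structure blocks ------------------------------------------------------

run_lengths <- function(mask) {
  if (!any(mask)) return(integer(0))
  r <- rle(mask)
  r$lengths[r$values]
}

run_stats <- function(mask, n, thresholds) {
  lens <- run_lengths(mask)
  c(vapply(thresholds, function(t) sum(lens >= t) / n, numeric(1)),
    if (length(lens) > 0L) max(lens) else 0,
    if (length(lens) > 0L) mean(lens) else 0)
}

freq_or_zero <- function(counts) {
  s <- sum(counts)
  if (s == 0) counts * 0 else counts / s
}

#' Annotation-derived structure features
#'
#' 145 deterministic summary features over the three per-residue tracks:
#' an exposure block (65: exposed fraction, amino-acid and five-class
#' frequencies among exposed/buried residues, and run statistics of the
#' exposed and buried segments), a secondary-structure block (37: state
#' fractions, per-state segment statistics and run counts, per-state
#' amino-acid-class frequencies, total segment density), a disorder block
#' (13: disordered fraction, segment statistics, long-run counts, overlap
#' with each secondary-structure state, terminal disorder), a
#' cross-combination block (20: five-class frequencies among disordered
#' residues, exposure-by-state and disorder-by-exposure overlaps,
#' exposed/buried His and Glu frequencies, per-state mean hydropathy of
#' exposed residues) and 10 sequence-global features (length, log-length,
#' isoelectric point, mean residue mass, mean hydropathy, per-residue net
#' charge, charge balance, aromatic and sulfur fractions, Cys-count
#' parity).
#'
#' @param sequence Amino-acid sequence string.
#' @param ss,disorder,exposure Annotation track strings (all required).
#' @return Named numeric vector of length 145.
#' @export
encode_structure_blocks <- function(sequence, ss, disorder, exposure) {
  row <- list(id = "", sequence = sequence, ss = ss, disorder = disorder,
              exposure = exposure)
  tr <- annotation_tracks(row)
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  five <- five_class_alphabet()
  expmask <- tr$exposure == "E"
  dismask <- tr$disorder == "D"

  # exposure block (65)
  exp_counts <- aa_counts(chars[expmask])
  bur_counts <- aa_counts(chars[!expmask])
  exposure_block <- c(
    mean(expmask),
    freq_or_zero(exp_counts), freq_or_zero(bur_counts),
    freq_or_zero(tabulate(five[chars[expmask]], 5L)),
    freq_or_zero(tabulate(five[chars[!expmask]], 5L)),
    run_stats(expmask, n, c(1, 2, 4, 8, 16)),
    run_stats(!expmask, n, c(1, 2, 4, 8, 16))
  )

  # secondary-structure block (37)
  states <- c("H", "E", "C")
  ss_block <- tabulate(match(tr$ss, states), 3L) / n
  seg_stats <- class_freqs <- run_feats <- NULL
  for (st in states) {
    lens <- run_lengths(tr$ss == st)
    seg_stats <- c(seg_stats,
                   if (length(lens)) mean(lens) else 0,
                   if (length(lens)) max(lens) else 0,
                   length(lens) / n)
    run_feats <- c(run_feats,
                   vapply(c(1, 4, 8), function(t) sum(lens >= t) / n,
                          numeric(1)))
    in_state <- chars[tr$ss == st]
    class_freqs <- c(class_freqs, vapply(SS_AA_CLASSES, function(cls) {
      if (length(in_state) == 0L) 0 else mean(in_state %in% cls)
    }, numeric(1)))
  }
  total_segs <- length(rle(tr$ss)$lengths) / n
  ss_block <- c(ss_block, seg_stats, run_feats, class_freqs, total_segs)

  # disorder block (13)
  dlens <- run_lengths(dismask)
  nterm <- seq_len(min(20L, n))
  cterm <- seq.int(max(1L, n - 19L), n)
  disorder_block <- c(
    mean(dismask),
    length(dlens) / n,
    if (length(dlens)) mean(dlens) else 0,
    if (length(dlens)) max(dlens) else 0,
    vapply(c(4, 8, 16, 32), function(t) sum(dlens >= t) / n, numeric(1)),
    vapply(states, function(st) mean(dismask & tr$ss == st), numeric(1)),
    mean(dismask[nterm]), mean(dismask[cterm])
  )

  # cross-combination block (20)
  kd <- KD_HYDROPATHY[chars]
  cross_block <- c(
    freq_or_zero(tabulate(five[chars[dismask]], 5L)),
    vapply(states, function(st) mean(expmask & tr$ss == st), numeric(1)),
    vapply(states, function(st) mean(!expmask & tr$ss == st), numeric(1)),
    mean(dismask & expmask), mean(dismask & !expmask),
    mean(expmask & chars == "H"), mean(!expmask & chars == "E"),
    mean(expmask & chars == "E"), mean(!expmask & chars == "H"),
    vapply(states, function(st) {
      sel <- expmask & tr$ss == st
      if (any(sel)) mean(kd[sel]) else 0
    }, numeric(1))
  )

  # sequence-global block (10)
  counts <- aa_counts(chars)
  seqglobal <- c(
    n, log(n), compute_pi(sequence),
    mean(RESIDUE_MASS[chars]), mean(kd),
    net_charge_at(7, counts) / n,
    (sum(counts[c("K", "R")]) - sum(counts[c("D", "E")])) / n,
    sum(counts[c("F", "W", "Y")]) / n,
    sum(counts[c("C", "M")]) / n,
    counts[["C"]] %% 2
  )

  reg <- feature_registry()
  # registry order among these blocks is seqglobal, exposure, ss, disorder,
  # cross, matching the concatenation below
  out <- c(seqglobal, exposure_block, ss_block, disorder_block, cross_block)
  names(out) <- reg$feature_id[reg$block %in%
    c("seqglobal", "exposure", "ss", "disorder", "cross")]
  out
}

# ---- full encoder ----------------------------------------------------------

#' Encode proteins into the full 2,924-feature table
#'
#' Concatenates every feature block in registry order for each protein.
#' All three annotation tracks must be present (use [annotate_baseline()]
#' or [parse_annotation()] first). The encoding is a pure function of
#' (sequence, annotation, parameters): identical inputs give bit-identical
#' rows.
#'
#' @param proteins Tibble with `id`, `sequence` and annotation columns
#'   `ss`, `disorder`, `exposure`.
#' @param aaindex AAindex table (default: bundled 544-entry snapshot).
#' @param autocorr,qso,apaac Parameter lists for the corresponding
#'   descriptor families.
#' @return A tibble with `id` plus 2,924 feature columns named by the
#'   registry.
#' @export
encode_features <- function(proteins, aaindex = aaindex_table(),
                            autocorr = autocorr_params(),
                            qso = qso_params(), apaac = apaac_params()) {
  reg <- feature_registry(aaindex)
  need <- setdiff(c("ss", "disorder", "exposure"), names(proteins))
  if (length(need) > 0L) {
    stop("missing annotation track(s): ", paste(need, collapse = ", "),
         "; run annotate_baseline() first", call. = FALSE)
  }
  one <- function(i) {
    s <- proteins$sequence[[i]]
    v <- c(
      encode_aaindex_blocks(s, proteins$exposure[[i]], aaindex),
      encode_dipeptide(s),
      encode_autocorrelation(s, autocorr, aaindex),
      encode_ctd(s),
      encode_qso(s, qso),
      encode_apaac(s, apaac),
      encode_taap(s, autocorr, aaindex),
      encode_structure_blocks(s, proteins$ss[[i]], proteins$disorder[[i]],
                              proteins$exposure[[i]]),
      encode_compositions(s)
    )
    unname(v[reg$feature_id])
  }
  mat <- t(vapply(seq_len(nrow(proteins)), one, numeric(nrow(reg))))
  colnames(mat) <- reg$feature_id
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop("non-finite feature value: feature '", reg$feature_id[bad[[2L]]],
         "' of record '", proteins$id[[bad[[1L]]]], "'", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  tibble::add_column(out, id = proteins$id, .before = 1L)
}
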