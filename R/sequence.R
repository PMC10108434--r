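#' Net charge of an amino-acid sequence
#'
#' Integer charge counting at neutral pH: +1 per lysine or arginine, -1 per
#' aspartate or glutamate; histidine, termini and pKa shifts are ignored.
#' This matches how surface charge is usually tallied for domain comparisons.
#'
#' @param sequence One-letter amino-acid string (may include `X`; gaps `-`
#'   are ignored).
#' @param region Optional integer range (e.g. `10:69`) restricting the count
#'   to part of the sequence. Positions index the ungapped string as given.
#' @return Tibble with columns `n_D`, `n_E`, `n_K`, `n_R`, `net_charge`.
#' @export
#' @examples
#' net_charge("DEKR") # 0
net_charge <- function(sequence, region = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  ok <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-", ".")
  if (!all(chars %in% ok)) {
    abort(sprintf("Invalid characters in sequence: %s",
                  paste(unique(setdiff(chars, ok)), collapse = ", ")))
  }
  if (!is.null(region)) {
    region <- region[region >= 1 & region <= length(chars)]
    chars <- chars[region]
  }
  n_D <- sum(chars == "D"); n_E <- sum(chars == "E")
  n_K <- sum(chars == "K"); n_R <- sum(chars == "R")
  tibble(n_D = n_D, n_E = n_E, n_K = n_K, n_R = n_R,
         net_charge = (n_K + n_R) - (n_D + n_E))
}

#' Per-sequence charge profile and group summary for an alignment
#'
#' Counts charged residues per row (gaps excluded) and summarises the net
#' charge across the alignment with a normal-approximation 95% confidence
#' interval on the mean.
#'
#' @param alignment Data frame with columns `id` and `sequence` (equal-length
#'   gapped strings), or a character vector of sequences.
#' @param region Optional integer range of alignment columns to count.
#' @return Object of class `charge_profile`: list with `per_sequence` (tibble:
#'   `id`, `n_D`, `n_E`, `n_K`, `n_R`, `net_charge`) and `summary` (tibble:
#'   `mean_net_charge`, `ci95_halfwidth`, `n`).
#' @export
alignment_charge_stats <- function(alignment, region = NULL) {
  aln <- .as_alignment(alignment)
  M <- aln$M
  if (nrow(M) < 2) abort("Need at least 2 aligned sequences.")
  if (!is.null(region) && (min(region) < 1 || max(region) > ncol(M))) {
    abort("`region` lies outside the alignment.")
  }
  per <- purrr::map(seq_len(nrow(M)), function(i) {
    chars <- M[i, ]
    if (!is.null(region)) chars <- chars[region]
    chars <- chars[!chars %in% c("-", ".")]
    net_charge(paste0(chars, collapse = ""))
  }) |> purrr::list_rbind()
  per <- per |> mutate(id = aln$id, .before = 1)
  structure(
    list(
      per_sequence = per,
      summary = tibble(
        mean_net_charge = mean(per$net_charge),
        ci95_halfwidth = ci95_halfwidth(per$net_charge),
        n = nrow(per)
      )
    ),
    class = "charge_profile"
  )
}

#' @export
print.charge_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<charge_profile> %d sequences, mean net charge %.2f +/- %.2f (95%% CI)\n",
              s$n, s$mean_net_charge, s$ci95_halfwidth))
  invisible(x)
}

# normalize alignment input to list(id, matrix = list(char matrix))
.as_alignment <- function(alignment) {
  if (is.character(alignment)) {
    alignment <- tibble(id = sprintf("seq_%03d", seq_along(alignment)),
                        sequence = alignment)
  }
  stopifnot(is.data.frame(alignment),
            all(c("id", "sequence") %in% names(alignment)))
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) != 1) abort("Aligned sequences must share one length.")
  M <- do.call(rbind, strsplit(toupper(alignment$sequence), ""))
  list(id = alignment$id, M = M)
}

# ---- covariation ------------------------------------------------------------

# all-pairs joint entropies via one-hot crossprod; gaps are a 21st symbol
.pair_entropy_engine <- function(M) {
  n <- nrow(M); L <- ncol(M)
  codes <- vector("list", L); k <- integer(L)
  for (j in seq_len(L)) {
    u <- sort(unique(M[, j]))
    k[j] <- length(u)
    codes[[j]] <- match(M[, j], u)
  }
  tot <- sum(k)
  off <- c(0L, cumsum(k))[seq_len(L)]
  X <- matrix(0, n, tot)
  X[cbind(rep(seq_len(n), L),
          rep(off, each = n) + unlist(codes))] <- 1
  G <- matrix(0, tot, L)
  for (j in seq_len(L)) G[(off[j] + 1):(off[j] + k[j]), j] <- 1
  Hm <- vapply(seq_len(L), function(j) {
    p <- tabulate(codes[[j]], k[j]) / n
    -sum(.plogp(p))
  }, numeric(1))
  list(X = X, G = G, k = k, off = off, n = n, L = L, Hm = Hm)
}

.plogp <- function(p) {
  out <- p * log2(p)
  out[p == 0] <- 0
  out
}

# L x L matrix of pairwise MI (bits) from a one-hot matrix
.mi_matrix <- function(X, eng) {
  C <- crossprod(X) / eng$n
  Hj <- -crossprod(eng$G, .plogp(C)) %*% eng$G
  MI <- outer(eng$Hm, eng$Hm, "+") - Hj
  diag(MI) <- 0
  # clip tiny negative rounding noise
  MI[MI < 0] <- 0
  MI
}

# average-product correction
.apc <- function(MI) {
  L <- ncol(MI)
  mi_col <- rowSums(MI) / (L - 1)
  mi_mean <- sum(MI[upper.tri(MI)]) / (L * (L - 1) / 2)
  if (mi_mean <= 0) return(MI)
  MI - outer(mi_col, mi_col) / mi_mean
}

#' Mutual-information covariation scan of an alignment
#'
#' Computes mutual information (bits; gaps treated as a 21st symbol) for every
#' column pair, applies the average-product correction
#' `MI_apc(i,j) = MI - MI_i * MI_j / MI_mean`, and assigns p-values from a
#' permutation null built by shuffling every column independently
#' `n_permutations` times; the shuffled APC statistics of all pairs are pooled
#' into one null distribution (columns are exchangeable under the
#' independence null, and pooling gives the resolution that per-pair nulls
#' cannot). Benjamini-Hochberg controls the FDR across pairs.
#'
#' @param alignment Data frame with `id`, `sequence` columns (see
#'   [alignment_charge_stats()]); at least 20 rows.
#' @param n_permutations Number of within-column shuffle rounds (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return Object of class `covariation_result`: tibble with columns `pos_i`,
#'   `pos_j`, `mi_bits`, `mi_apc`, `p_value`, `q_value`, sorted by `q_value`.
#' @export
#' @examples
#' aln <- sim_alignment(n_seqs = 50, length = 10, charge_target = -2,
#'                      covarying_pair = c(3, 8), seed = 1)
#' head(covariation_mi(aln, n_permutations = 100, seed = 1), 3)
covariation_mi <- function(alignment, n_permutations = 1000, seed = 1) {
  aln <- .as_alignment(alignment)
  M <- aln$M
  if (ncol(M) < 2) abort("Alignment must have at least 2 columns.")
  if (nrow(M) < 20) abort("Need >= 20 rows for a meaningful permutation null.")
  check_number(n_permutations, "n_permutations", lower = 1)

  eng <- .pair_entropy_engine(M)
  obs_mi <- .mi_matrix(eng$X, eng)
  obs_apc <- .apc(obs_mi)
  ut <- upper.tri(obs_apc)
  obs_v <- obs_apc[ut]

  null_v <- with_local_seed(seed, {
    out <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      Xp <- eng$X
      for (j in seq_len(eng$L)) {
        cols <- (eng$off[j] + 1):(eng$off[j] + eng$k[j])
        Xp[, cols] <- eng$X[sample.int(eng$n), cols, drop = FALSE]
      }
      nm <- .apc(.mi_matrix(Xp, eng))
      out[[b]] <- nm[ut]
    }
    unlist(out)
  })
  # pooled permutation p-values (add-one rule keeps them conservative)
  srt <- sort(null_v)
  exceed <- length(null_v) - findInterval(obs_v, srt, left.open = TRUE)
  p <- (1 + exceed) / (length(null_v) + 1)
  q <- p.adjust(p, method = "BH")

  idx <- which(ut, arr.ind = TRUE)
  out <- tibble(
    pos_i = idx[, 1], pos_j = idx[, 2],
    mi_bits = obs_mi[ut], mi_apc = obs_v,
    p_value = p, q_value = q
  ) |> arrange(.data$q_value, desc(.data$mi_apc))
  class(out) <- c("covariation_result", class(out))
  out
}

# ---- FASTA I/O ---------------------------------------------------------------

#' Read sequences or an alignment from FASTA
#'
#' @param path FASTA file (plain or aligned).
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(id = names(x), sequence = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)))
  x <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
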