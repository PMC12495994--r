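sample_key <- function(s) paste(s$lnc, s$mi, s$mr, s$dis, sep = "\r")

#' Candidate diseases for a negative sample of a triplet
#'
#' All diseases not positively associated with the triplet. A triplet that
#' is positively associated with every disease is "fully associated" and has
#' an empty candidate set; the sampler handles it by re-drawing the seed
#' triplet.
#'
#' @param triplet list or one-row data.frame with `lnc`, `mi`, `mr`.
#' @param positives data.frame of positive samples (`lnc`, `mi`, `mr`,
#'   `dis`).
#' @param all_diseases character vector of every disease id.
#' @return Character vector of candidate diseases (possibly empty).
#' @export
candidate_diseases <- function(triplet, positives, all_diseases) {
  if (!length(all_diseases)) stop_config("empty disease universe")
  hit <- positives$lnc == triplet$lnc & positives$mi == triplet$mi &
    positives$mr == triplet$mr
  setdiff(all_diseases, positives$dis[hit])
}

#' Structure-consistent negative sampling
#'
#' Generates label-0 (triplet, disease) samples that are structurally valid:
#' each negative is seeded by a uniformly drawn positive, keeps that
#' positive's miRNA fixed, replaces the lncRNA and mRNA with uniform draws
#' from the nodes having validated interactions with the same miRNA (the
#' original partners included), and pairs the triplet with a disease not
#' positively associated with it. Stratification keeps the node-type
#' marginals close to the positives: seed triplets are drawn uniformly from
#' the positive set (so the miRNA marginal matches by construction) and a
#' per-disease quota caps any disease at `ceil(2 n / n_diseases_in_positives)`.
#' Sampled quadruples never overlap the positives and are not repeated.
#'
#' @param positives data.frame of positive samples (`lnc`, `mi`, `mr`,
#'   `dis`).
#' @param lnc_mi data.frame of validated lncRNA--miRNA interactions
#'   (columns `lnc`, `mi`).
#' @param mi_mr data.frame of validated miRNA--mRNA interactions (columns
#'   `mi`, `mr`).
#' @param all_diseases character vector of the complete disease set.
#' @param n number of negatives to draw.
#' @param seed integer seed; equal seeds give identical output.
#' @param max_tries retry bound (default `100 * n`) before raising a
#'   sampler-exhaustion error with diagnostic counts.
#' @return data.frame with columns `lnc`, `mi`, `mr`, `dis`, `label` (0).
#' @export
sample_negatives <- function(positives, lnc_mi, mi_mr, all_diseases, n,
                             seed = 1L, max_tries = 100 * n) {
  if (n < 1) stop_config("n must be >= 1")
  if (nrow(lnc_mi) == 0 || nrow(mi_mr) == 0) {
    stop_config("interaction lists must be non-empty")
  }
  lnc_by_mi <- split(lnc_mi$lnc, lnc_mi$mi)
  mr_by_mi <- split(mi_mr$mr, mi_mr$mi)
  pos_keys <- unique(sample_key(positives))
  # positive diseases per triplet, for candidate lookup
  trip_key <- paste(positives$lnc, positives$mi, positives$mr, sep = "\r")
  dis_by_trip <- split(positives$dis, trip_key)
  quota <- ceiling(2 * n / length(unique(positives$dis)))
  dis_count <- integer(0)

  set.seed(derive_seed(seed, "negative-sampler"))
  out_l <- character(n); out_m <- character(n); out_r <- character(n)
  out_d <- character(n)
  got <- 0L; tries <- 0L; fully_associated <- 0L; duplicates <- 0L
  seen <- character(0)
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_config(paste0(
        "negative sampler exhausted after %d tries (drawn %d of %d; ",
        "%d fully-associated redraws, %d duplicate rejections)"),
        tries - 1L, got, n, fully_associated, duplicates)
    }
    k <- sample.int(nrow(positives), 1L)
    mi <- positives$mi[k]
    lnc_cand <- lnc_by_mi[[mi]]
    mr_cand <- mr_by_mi[[mi]]
    if (is.null(lnc_cand) || is.null(mr_cand)) next
    lnc <- lnc_cand[sample.int(length(lnc_cand), 1L)]
    mr <- mr_cand[sample.int(length(mr_cand), 1L)]
    tk <- paste(lnc, mi, mr, sep = "\r")
    cand <- setdiff(all_diseases, dis_by_trip[[tk]])
    if (!length(cand)) {
      fully_associated <- fully_associated + 1L
      next
    }
    dis <- cand[sample.int(length(cand), 1L)]
    cnt <- dis_count[dis]
    if (!is.na(cnt) && cnt >= quota) next
    key <- paste(tk, dis, sep = "\r")
    if (key %in% pos_keys || key %in% seen) {
      duplicates <- duplicates + 1L
      next
    }
    got <- got + 1L
    out_l[got] <- lnc; out_m[got] <- mi; out_r[got] <- mr; out_d[got] <- dis
    seen <- c(seen, key)
    dis_count[dis] <- if (is.na(cnt)) 1L else cnt + 1L
  }
  data.frame(lnc = out_l, mi = out_m, mr = out_r, dis = out_d,
             label = 0L, stringsAsFactors = FALSE)
}

#' Uniform random negative sampling (baseline)
#'
#' Draws (lncRNA, miRNA, mRNA, disease) quadruples uniformly from the node
#' sets, rejecting known positives and repeats, with no structural validity
#' requirement. Serves as the ablation baseline for the structure-consistent
#' sampler.
#'
#' @param positives data.frame of positive samples.
#' @param hg a [hetero_graph()].
#' @param n number of negatives.
#' @param seed integer seed.
#' @return data.frame with columns `lnc`, `mi`, `mr`, `dis`, `label` (0).
#' @export
sample_negatives_random <- function(positives, hg, n, seed = 1L) {
  set.seed(derive_seed(seed, "random-negative-sampler"))
  pos_keys <- unique(sample_key(positives))
  out <- list(); got <- 0L; tries <- 0L
  seen <- character(0)
  while (got < n) {
    tries <- tries + 1L
    if (tries > 1000 * n) stop_config("random negative sampler exhausted")
    s <- list(lnc = sample(hg$nodes$lnc, 1L), mi = sample(hg$nodes$mi, 1L),
              mr = sample(hg$nodes$mr, 1L), dis = sample(hg$nodes$dis, 1L))
    key <- sample_key(s)
    if (key %in% pos_keys || key %in% seen) next
    got <- got + 1L
    out[[got]] <- s
    seen <- c(seen, key)
  }
  cbind(do.call(rbind.data.frame, out), label = 0L)
}
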