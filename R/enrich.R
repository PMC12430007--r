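#' @importFrom stats phyper
NULL

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of `hits` within an
#' explicit `background` (sets are intersected with the background before
#' testing; there is no implicit genome-wide default). The p-value is the
#' upper-tail hypergeometric probability `P(X >= overlap)`; with
#' `ease = TRUE` an EASE-style conservative variant is used (one hit
#' removed from the overlap, as in DAVID's modified Fisher test). P-values
#' are BH-corrected across sets.
#'
#' @param hits character vector of hit symbols (subset of `background`)
#' @param background character vector; the tested universe
#' @param sets a `GeneSetCollection` (named list of member vectors)
#' @param ease use the overlap-minus-one variant (default FALSE)
#' @return data.frame: set_id, overlap, set_size_in_background, n_hits,
#'   n_background, p, fdr; hit members per set attached as the
#'   `"hit_members"` attribute (named list)
#' @export
hypergeometric_ora <- function(hits, background, sets, ease = FALSE) {
  background <- unique(background)
  hits <- unique(hits)
  if (!length(background)) stop("background must be non-empty")
  if (!all(hits %in% background))
    stop("hits must be a subset of the background")
  N <- length(background)
  K <- length(hits)
  rows <- vector("list", length(sets))
  hit_members <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    mem <- intersect(unique(sets[[i]]), background)
    ov <- intersect(mem, hits)
    q <- length(ov) - if (ease) 1L else 0L
    p <- phyper(max(q, 0) - 1L, length(mem), N - length(mem), K,
                lower.tail = FALSE)
    rows[[i]] <- data.frame(set_id = names(sets)[i], overlap = length(ov),
                            set_size_in_background = length(mem),
                            n_hits = K, n_background = N, p = p,
                            stringsAsFactors = FALSE)
    hit_members[[i]] <- ov
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(), overlap = integer(),
                      set_size_in_background = integer(),
                      n_hits = integer(), n_background = integer(),
                      p = numeric(), fdr = numeric())
  if (nrow(out)) out$fdr <- bh_adjust(out$p)
  names(hit_members) <- names(sets)
  rownames(out) <- NULL
  attr(out, "hit_members") <- hit_members
  out
}

#' Redundancy pruning and size filtering of ORA results
#'
#' Walks the results from most to least significant p-value. A set is
#' retained only if it is significant (`fdr < fdr_max`), has at least
#' `min_hits` hit members, no more than `max_set_size` members in the
#' background, and contributes at least `min_novel` hit members not
#' already covered by a previously retained (more significant) set.
#'
#' @param results data.frame from [hypergeometric_ora()] (its
#'   `"hit_members"` attribute must be present)
#' @param min_novel minimum uncovered hit members (default 2)
#' @param min_hits minimum hit members (default 5; transcriptome stages
#'   use 2, single-cell hallmark stages use 2)
#' @param max_set_size maximum set size in the background (default 300;
#'   `Inf` disables)
#' @param fdr_max significance cut (default 0.05)
#' @return `results` with logical `retained` and character `absorbed_by`
#'   columns (the earlier set that covered a pruned set's members)
#' @export
prune_and_filter <- function(results, min_novel = 2, min_hits = 5,
                             max_set_size = 300, fdr_max = 0.05) {
  hm <- attr(results, "hit_members")
  if (is.null(hm)) stop("results lack the hit_members attribute")
  ord <- order(results$p, results$set_id)
  covered <- character()
  covered_by <- list()
  retained <- logical(nrow(results))
  absorbed <- rep(NA_character_, nrow(results))
  for (i in ord) {
    mem <- hm[[results$set_id[i]]]
    novel <- setdiff(mem, covered)
    ok <- results$fdr[i] < fdr_max &&
      results$overlap[i] >= min_hits &&
      results$set_size_in_background[i] <= max_set_size &&
      length(novel) >= min_novel
    if (ok) {
      retained[i] <- TRUE
      covered_by[novel] <- results$set_id[i]
      covered <- union(covered, mem)
    } else if (length(mem) && !length(novel)) {
      prev <- unique(unlist(covered_by[mem], use.names = FALSE))
      absorbed[i] <- paste(prev, collapse = ",")
    }
  }
  results$retained <- retained
  results$absorbed_by <- absorbed
  results
}
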