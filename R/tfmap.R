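#' Known transcription-factor regulatory network
#'
#' @param edges data frame with columns `tf`, `target`, `effect`
#'   (`"activation"`, `"repression"` or `"dual"`).
#' @param universe character vector of assayed promoters forming the finite
#'   population for enrichment tests (typically the active promoters that
#'   are annotated in the network source).
#' @return Object of class `"regulatory_network"`; edges whose target lies
#'   outside the universe are kept separately in `off_universe`.
#' @export
regulatory_network <- function(edges, universe) {
  stopifnot(is.data.frame(edges),
            all(c("tf", "target", "effect") %in% names(edges)))
  bad <- setdiff(edges$effect, c("activation", "repression", "dual"))
  if (length(bad)) {
    stop("unknown effect token(s): ", paste(bad, collapse = ", "),
         "; allowed: activation, repression, dual", call. = FALSE)
  }
  if (anyDuplicated(edges[, c("tf", "target")])) {
    stop("duplicate (tf, target) edge", call. = FALSE)
  }
  if (!length(universe)) stop("empty promoter universe", call. = FALSE)
  off <- edges[!edges$target %in% universe, , drop = FALSE]
  edges <- edges[edges$target %in% universe, , drop = FALSE]
  structure(list(edges = edges, universe = unique(universe),
                 off_universe = off),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d edges, %d TFs, universe of %d promoters",
              nrow(x$edges), length(unique(x$edges$tf)), length(x$universe)))
  if (nrow(x$off_universe)) {
    cat(sprintf(" (%d off-universe edges set aside)", nrow(x$off_universe)))
  }
  cat("\n")
  invisible(x)
}

#' Load a TF -> promoter edge list from a TSV file
#'
#' Expects tab-separated columns `tf`, `target`, `effect` (RegulonDB-style
#' export). Malformed rows are reported with their line number.
#'
#' @param path TSV path.
#' @param universe assayed promoter universe (see [regulatory_network()]).
#' @return A [regulatory_network()].
#' @export
load_network <- function(path, universe) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "effect")
  if (!all(need %in% names(tab))) {
    stop("network file must have columns tf, target, effect", call. = FALSE)
  }
  bad <- which(!stats::complete.cases(tab[, need]) |
                 tab$tf == "" | tab$target == "")
  if (length(bad)) {
    stop("malformed network row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  net <- regulatory_network(tab[, need], universe)
  if (nrow(net$off_universe)) {
    message(nrow(net$off_universe),
            " edge(s) target promoters outside the assayed universe")
  }
  net
}

#' Map an inferred regulatory metabolite to a transcription factor
#'
#' For a metabolite inferred to regulate a set of promoters, computes the
#' overlap of that target set with each transcription factor's known targets
#' (`overlap_fraction = |targets in regulon| / |targets|`; 1 means every
#' metabolite target is regulated by the TF). The TF with the largest overlap
#' is selected (ties broken by smaller enrichment p, then lexicographic id)
#' and its enrichment is assessed by a one-sided hypergeometric test over the
#' assayed universe. Dual-effect edges count toward the overlap regardless of
#' the inferred sign. Metabolites with two or fewer targets should be skipped
#' by the caller, as enrichment is unstable for such small draws.
#'
#' @param metabolite_targets character vector of inferred target promoters
#'   (must have more than 2 members).
#' @param network a [regulatory_network()].
#' @param p_cutoff significance threshold on the enrichment p-value,
#'   default 0.1.
#' @return Data frame of class `"enrichment_result"` with one row per TF:
#'   `tf_id`, `n_tf_targets`, `n_overlap`, `overlap_fraction`, `p_value`,
#'   `selected`, `significant`.
#' @export
map_metabolite_to_tf <- function(metabolite_targets, network, p_cutoff = 0.1) {
  stopifnot(inherits(network, "regulatory_network"))
  targets <- intersect(unique(metabolite_targets), network$universe)
  if (length(targets) <= 2L) {
    stop("metabolite has 2 or fewer targets in the universe; skipped",
         call. = FALSE)
  }
  N <- length(network$universe)
  n_draw <- length(targets)
  tfs <- sort(unique(network$edges$tf))
  res <- do.call(rbind, lapply(tfs, function(tf) {
    regulon <- unique(network$edges$target[network$edges$tf == tf])
    K <- length(regulon)
    ov <- length(intersect(targets, regulon))
    data.frame(tf_id = tf, n_tf_targets = K, n_overlap = ov,
               overlap_fraction = ov / n_draw,
               p_value = stats::phyper(ov - 1L, K, N - K, n_draw,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$overlap_fraction, res$p_value, res$tf_id), ]
  res$selected <- seq_len(nrow(res)) == 1L
  res$significant <- res$selected & res$p_value < p_cutoff
  rownames(res) <- NULL
  attr(res, "n_metabolite_targets") <- n_draw
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  top <- x[x$selected, ]
  cat(sprintf("Selected TF: %s (overlap %.0f%%, p = %.3g%s)\n",
              top$tf_id, 100 * top$overlap_fraction, top$p_value,
              if (top$significant) ", significant" else ""))
  print.data.frame(utils::head(x, 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Recovery of reported promoter-metabolite interactions
#'
#' For each reported interaction, correlates the metabolite's profile with
#' the promoter's activity both after (`r_specific`) and before (`r_raw`)
#' removal of global regulation, over the metabolite's unmasked conditions.
#' An interaction counts as recovered when the signed correlation passes the
#' cutoff in the direction implied by the reported effect (activation:
#' `r >= cutoff`; repression: `r <= -cutoff`; dual: `|r| >= cutoff`).
#' Interactions with fewer than 3 usable conditions are excluded and counted
#' separately. The four sector fractions plus the excluded fraction sum to 1.
#'
#' @param reported data frame with columns `metabolite_id`, `target`
#'   (promoter id), `effect`, and optionally `tf_id`.
#' @param S specific-regulation matrix (promoters x conditions).
#' @param X normalized activity matrix with matching dimnames.
#' @param M a [metabolite_table()].
#' @param cutoff absolute correlation cutoff, default 0.75.
#' @return List: `table` (per-interaction correlations and sector),
#'   `fractions` (named: `both`, `only_with_removal`, `only_without_removal`,
#'   `neither`, `excluded`, as fractions of all reported interactions), and
#'   `n_reported`.
#' @export
recovery_quadrants <- function(reported, S, X, M, cutoff = 0.75) {
  stopifnot(inherits(M, "metabolite_table"),
            all(c("metabolite_id", "target", "effect") %in% names(reported)))
  rows <- lapply(seq_len(nrow(reported)), function(i) {
    met <- reported$metabolite_id[i]
    prom <- reported$target[i]
    eff <- reported$effect[i]
    if (!met %in% M$metabolites || !prom %in% rownames(S)) {
      return(data.frame(metabolite_id = met, target = prom, effect = eff,
                        r_specific = NA_real_, r_raw = NA_real_,
                        sector = "excluded", stringsAsFactors = FALSE))
    }
    use <- !M$mask[met, ] & is.finite(M$M[met, ])
    if (sum(use) < 3L) {
      return(data.frame(metabolite_id = met, target = prom, effect = eff,
                        r_specific = NA_real_, r_raw = NA_real_,
                        sector = "excluded", stringsAsFactors = FALSE))
    }
    m <- M$M[met, use]
    rs <- stats::cor(S[prom, use], m)
    rr <- stats::cor(X[prom, use], m)
    pass <- function(r) {
      switch(eff,
             activation = r >= cutoff,
             repression = r <= -cutoff,
             dual = abs(r) >= cutoff,
             stop("unknown effect: ", eff, call. = FALSE))
    }
    sector <- if (pass(rs) && pass(rr)) "both"
    else if (pass(rs)) "only_with_removal"
    else if (pass(rr)) "only_without_removal"
    else "neither"
    data.frame(metabolite_id = met, target = prom, effect = eff,
               r_specific = rs, r_raw = rr, sector = sector,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sectors <- c("both", "only_with_removal", "only_without_removal",
               "neither", "excluded")
  fr <- vapply(sectors, function(s) mean(tab$sector == s), numeric(1))
  list(table = tab, fractions = fr, n_reported = nrow(tab))
}
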