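#' Classify the ecological interaction of a pair experiment
#'
#' Derives, from a completed \code{pair_experiment}:
#' \itemize{
#'   \item \strong{competition}: some primary carbon source taken up
#'     (exchange flux at or below -0.01) by both organisms in the final
#'     iteration;
#'   \item \strong{exchange edges}: organism \code{i} gives metabolite
#'     \code{m} to \code{j} iff \code{i} secreted \code{m} costlessly in
#'     some iteration and \code{j} takes \code{m} up in its
#'     final-iteration minimal-flux solution, with \code{m} not on the
#'     exclusion list (water and protons by default: ubiquitous
#'     bookkeeping flows; CO2 and ammonium are deliberately \emph{not}
#'     excluded, being genuine enabling byproducts);
#'   \item \strong{interaction class}: N (no edges), C (edges one way),
#'     M (edges both ways);
#'   \item \strong{motif code}: class + number of primary carbon sources
#'     consumed by the pair + "b" under competition else "a", e.g.
#'     \code{"C1a"}.
#' }
#' Pairs in which both organisms did not grow are labelled
#' \code{"no-pair-growth"} and carry no motif.
#'
#' @param record a \code{pair_experiment}.
#' @param exclusion metabolite ids never counted as exchange edges.
#' @param defaults cutoffs, see \code{\link{fba_defaults}}.
#' @return object of class \code{interaction_label}: \code{status},
#'   \code{competition}, \code{iclass}, \code{direction},
#'   \code{n_carbons_consumed}, \code{motif_code},
#'   \code{exchange_edges} (data.frame giver/metabolite/receiver).
#' @export
classify_interaction <- function(record, exclusion = c("h2o_e", "h_e"),
                                 defaults = fba_defaults()) {
  stopifnot(inherits(record, "pair_experiment"))
  if (record$nonterminated)
    stop("record flagged nonterminated; refusing to classify")
  fin <- record$iterations[[record$c_s]]
  if (!all(fin$growth)) {
    return(structure(list(status = "no-pair-growth",
                          competition = NA, iclass = NA_character_,
                          direction = NA_character_,
                          n_carbons_consumed = NA_integer_,
                          motif_code = NA_character_,
                          exchange_edges = empty_edges()),
                     class = "interaction_label"))
  }
  carbons <- record$carbon_sources
  up_i <- names(fin$uptakes[[1]])
  up_j <- names(fin$uptakes[[2]])
  competition <- length(intersect(intersect(carbons, up_i), up_j)) > 0L
  n_carbons <- length(intersect(carbons, union(up_i, up_j)))

  sec_any <- function(org) setdiff(
    unique(unlist(lapply(record$iterations, function(it)
      names(it$secretions[[org]])))), exclusion)
  edges_ij <- intersect(sec_any(1L), up_j)
  edges_ji <- intersect(sec_any(2L), up_i)
  ids <- record$organisms
  edges <- rbind(
    if (length(edges_ij))
      data.frame(giver = ids[1], metabolite = edges_ij,
                 receiver = ids[2], stringsAsFactors = FALSE),
    if (length(edges_ji))
      data.frame(giver = ids[2], metabolite = edges_ji,
                 receiver = ids[1], stringsAsFactors = FALSE))
  if (is.null(edges)) edges <- empty_edges()
  has_ij <- length(edges_ij) > 0L
  has_ji <- length(edges_ji) > 0L
  iclass <- if (has_ij && has_ji) "M" else if (has_ij || has_ji) "C"
            else "N"
  direction <- if (has_ij && has_ji) "both"
               else if (has_ij) "i->j"
               else if (has_ji) "j->i" else "none"
  structure(list(status = "classified",
                 competition = competition,
                 iclass = iclass,
                 direction = direction,
                 n_carbons_consumed = n_carbons,
                 motif_code = paste0(iclass, n_carbons,
                                     if (competition) "b" else "a"),
                 exchange_edges = edges),
            class = "interaction_label")
}

empty_edges <- function()
  data.frame(giver = character(0), metabolite = character(0),
             receiver = character(0), stringsAsFactors = FALSE)

#' @export
print.interaction_label <- function(x, ...) {
  if (x$status != "classified") {
    cat("<interaction_label>", x$status, "\n")
  } else {
    cat(sprintf("<interaction_label> %s (%s, %d edge(s))\n",
                x$motif_code, x$direction, nrow(x$exchange_edges)))
  }
  invisible(x)
}

#' Obligate syntrophy flags of a pair experiment
#'
#' An organism is an obligate syntroph in an experiment when it cannot
#' grow alone on the starting medium but grows once its partner's
#' costless secretions are available.
#'
#' @param record a \code{pair_experiment} (carries solo growth from
#'   iteration 1).
#' @return named logical vector (one flag per organism).
#' @export
obligate_syntrophy <- function(record) {
  stopifnot(inherits(record, "pair_experiment"))
  fin <- record$iterations[[record$c_s]]
  stats::setNames(!record$solo_growth & fin$growth, record$organisms)
}

#' Cooperativity index of a carbon-source pair
#'
#' Difference between the normalized frequency of pairwise growth on both
#' carbon sources and the product of the normalized single-source
#' frequencies,
#' \deqn{C^{\alpha\beta} = g_{\alpha\beta}/\binom{N_{\alpha\beta}}{2} -
#'   \left[g_\alpha/\binom{N_\alpha}{2}\right]
#'   \left[g_\beta/\binom{N_\beta}{2}\right],}
#' where the normalizers count the organism pairs tested in each
#' condition.  Positive values mean the pair of carbon sources supports
#' growth beyond what each does alone.
#'
#' @param g_ab count of pair-growth simulations on the carbon pair.
#' @param g_a,g_b counts on the single sources.
#' @param N_ab,N_a,N_b organism counts defining the normalizers
#'   \code{choose(N, 2)}.
#' @return the index, a number between -1 and 1.
#' @export
#' @examples
#' cooperativity_index(45, 30, 60, 14, 14, 14) # ~0.2771
cooperativity_index <- function(g_ab, g_a, g_b, N_ab, N_a = N_ab,
                                N_b = N_ab) {
  for (N in c(N_ab, N_a, N_b))
    if (N < 2) stop("normalizer requires at least two organisms")
  norm <- c(choose(N_ab, 2), choose(N_a, 2), choose(N_b, 2))
  g <- c(g_ab, g_a, g_b)
  if (any(g < 0) || any(g > norm))
    stop("growth counts must lie in [0, choose(N, 2)]")
  g_ab / norm[1] - (g_a / norm[2]) * (g_b / norm[3])
}

parse_fluxset <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                  vapply(kv, `[[`, character(1), 1))
}

#' Summary tables of a sweep results table
#'
#' Produces the tallies underpinning the usual reporting figures:
#' distribution of the final iteration index, per-metabolite secretion
#' frequency, interaction and motif frequency tables, and a pairwise
#' Spearman rank correlation matrix of binary secretion indicators
#' (metabolite secreted by either organism, per simulation).  Metabolites
#' secreted in every simulation or in none have an undefined rank
#' correlation and are reported as \code{NA}.
#'
#' @param results data.frame from \code{\link{run_sweep}}.
#' @return list with \code{cs_distribution},
#'   \code{secretion_frequency}, \code{interaction_frequency},
#'   \code{motif_frequency}, \code{cosecretion_spearman}.
#' @export
summarize_sweep <- function(results) {
  if (!nrow(results)) stop("empty results table")
  cs_tab <- as.data.frame(table(c_s = results$c_s),
                          stringsAsFactors = FALSE)
  cs_tab$c_s <- as.integer(cs_tab$c_s)

  sec_sets <- lapply(seq_len(nrow(results)), function(i)
    union(names(parse_fluxset(results$secreted_i[i])),
          names(parse_fluxset(results$secreted_j[i]))))
  mets <- sort(unique(unlist(sec_sets)))
  sec_freq <- data.frame(
    metabolite = mets,
    n_simulations = vapply(mets, function(m)
      sum(vapply(sec_sets, function(s) m %in% s, logical(1))),
      integer(1)),
    stringsAsFactors = FALSE)
  rownames(sec_freq) <- NULL

  inter_tab <- as.data.frame(table(interaction = results$interaction),
                             stringsAsFactors = FALSE)
  grown <- results$motif != ""
  motif_tab <- as.data.frame(table(motif = results$motif[grown]),
                             stringsAsFactors = FALSE)

  spear <- NULL
  if (length(mets) >= 2L) {
    ind <- vapply(mets, function(m)
      vapply(sec_sets, function(s) as.numeric(m %in% s), numeric(1)),
      numeric(length(sec_sets)))
    suppressWarnings(
      spear <- stats::cor(ind, method = "spearman"))
    constant <- apply(ind, 2, function(x) length(unique(x)) == 1L)
    spear[constant, ] <- NA_real_
    spear[, constant] <- NA_real_
    diag(spear) <- ifelse(constant, NA_real_, 1)
  }
  list(cs_distribution = cs_tab,
       secretion_frequency = sec_freq,
       interaction_frequency = inter_tab,
       motif_frequency = motif_tab,
       cosecretion_spearman = spear)
}

#' Write sweep summary tables as TSVs
#' @param summary result of \code{\link{summarize_sweep}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_summary_tsvs <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  w(summary$cs_distribution, "cs_distribution.tsv")
  w(summary$secretion_frequency, "secretion_frequencies.tsv")
  w(summary$interaction_frequency, "interaction_frequencies.tsv")
  w(summary$motif_frequency, "motif_frequencies.tsv")
  if (!is.null(summary$cosecretion_spearman))
    utils::write.table(summary$cosecretion_spearman,
                       file.path(dir, "cosecretion_spearman.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
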