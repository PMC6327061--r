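#' Run one iterative pairwise cross-feeding experiment
#'
#' Emulates a co-culture: at each iteration both organisms are solved
#' independently on the current medium (no resource partitioning — each
#' sees the full medium), their costless secretions are pooled, and any
#' metabolites new to the medium are added as cross-fed compounds for the
#' next iteration.  The loop ends at the first iteration in which the
#' medium stops changing (or immediately if neither organism grows at
#' iteration 1); that final iteration index is \code{c_s}.  Termination
#' within (number of distinct external metabolites) iterations is
#' guaranteed because the medium grows monotonically within a finite
#' universe.
#'
#' @param model_i,model_j harmonized \code{metabolic_model}s.
#' @param medium0 starting \code{medium} (M_0).
#' @param oxygen_i,oxygen_j per-organism oxygen state
#'   (\code{"present"}/\code{"absent"}); defaults to the medium's flag.
#'   Mixing the two reproduces hybrid oxic-anoxic experiments.
#' @param max_iter iteration cap; defaults to the number of distinct
#'   external metabolites across both models.
#' @param defaults cutoffs, see \code{\link{fba_defaults}}.
#' @return object of class \code{pair_experiment}: per-iteration growth
#'   statuses, media, secretion and uptake sets; \code{c_s}; solo growth
#'   statuses (iteration 1 equals growth alone on M_0 because organisms
#'   are solved independently); \code{nonterminated} flag.
#' @export
#' @examples
#' pr <- make_motif_pair("C1a")
#' rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
#'                            "absent", "absent")
#' rec$c_s                      # 2
#' classify_interaction(rec)$motif_code  # "C1a"
run_pair_experiment <- function(model_i, model_j, medium0,
                                oxygen_i = NULL, oxygen_j = NULL,
                                max_iter = NULL,
                                defaults = fba_defaults()) {
  if (is.null(oxygen_i)) oxygen_i <- medium0$oxygen
  if (is.null(oxygen_j)) oxygen_j <- medium0$oxygen
  n_ext <- length(union(external_metabolites(model_i),
                        external_metabolites(model_j)))
  if (is.null(max_iter)) max_iter <- max(n_ext, 1L)
  medium <- medium0
  iterations <- list()
  nonterminated <- FALSE
  repeat {
    res_i <- costless_secretions(model_i, medium, oxygen_i, defaults)
    res_j <- costless_secretions(model_j, medium, oxygen_j, defaults)
    entry <- list(growth = c(res_i$grew, res_j$grew),
                  growth_rate = c(res_i$solution$growth_rate,
                                  res_j$solution$growth_rate),
                  secretions = list(res_i$secretions, res_j$secretions),
                  uptakes = list(res_i$uptakes, res_j$uptakes),
                  medium = medium)
    iterations[[length(iterations) + 1L]] <- entry
    if (!any(entry$growth)) break
    sec_union <- union(names(res_i$secretions), names(res_j$secretions))
    ex <- expand_medium(medium, sec_union)
    if (!ex$changed) break
    medium <- ex$medium
    if (length(iterations) >= max_iter) {
      nonterminated <- TRUE
      break
    }
  }
  structure(list(organisms = c(model_i$model_id, model_j$model_id),
                 carbon_sources = medium0$carbon_sources,
                 oxygen = c(oxygen_i, oxygen_j),
                 iterations = iterations,
                 c_s = length(iterations),
                 solo_growth = iterations[[1L]]$growth,
                 final_medium = medium,
                 nonterminated = nonterminated),
            class = "pair_experiment")
}

#' @export
print.pair_experiment <- function(x, ...) {
  fin <- x$iterations[[x$c_s]]
  cat(sprintf("<pair_experiment> %s + %s on {%s} (O2: %s/%s): c_s=%d, growth %d/%d\n",
              x$organisms[1], x$organisms[2],
              paste(x$carbon_sources, collapse = ","),
              x$oxygen[1], x$oxygen[2], x$c_s,
              fin$growth[1], fin$growth[2]))
  invisible(x)
}

#' Plan a combinatorial pairwise sweep
#'
#' Enumerates unordered distinct organism pairs x unordered distinct
#' carbon-source pairs x oxygen conditions.  The component sets are
#' materialized; individual configurations are indexed lazily through
#' \code{\link{sweep_config}} so plans spanning millions of
#' configurations stay cheap.
#'
#' @param models list of \code{metabolic_model}s, or a character vector of
#'   model ids for pure enumeration.
#' @param carbon_sources character vector of carbon-source ids.
#' @param oxygen_conditions subset of \code{c("present", "absent")}.
#' @param n_organisms organisms per experiment (N_M); pair execution
#'   supports 2, enumeration any value.
#' @param n_carbons carbon sources per experiment (N_CS).
#' @param base_metabolites base medium used when the plan is executed.
#' @param bound_policy see \code{\link{build_medium}}.
#' @return object of class \code{sweep_plan}.
#' @export
#' @examples
#' plan <- plan_sweep(sprintf("m%02d", 1:14), sprintf("c%03d", 1:108))
#' n_configs(plan) # 1051596
plan_sweep <- function(models, carbon_sources,
                       oxygen_conditions = c("present", "absent"),
                       n_organisms = 2L, n_carbons = 2L,
                       base_metabolites = toy_base_medium(),
                       bound_policy = list()) {
  ids <- if (is.character(models)) models
         else vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) stop("duplicate model ids")
  if (length(ids) < n_organisms) stop("need at least ", n_organisms,
                                      " models")
  if (length(unique(carbon_sources)) != length(carbon_sources))
    stop("duplicate carbon sources")
  if (length(carbon_sources) < n_carbons)
    stop("need at least ", n_carbons, " carbon sources")
  stopifnot(all(oxygen_conditions %in% c("present", "absent")))
  org_pairs <- utils::combn(ids, n_organisms)
  carb_pairs <- utils::combn(carbon_sources, n_carbons)
  structure(list(models = if (is.character(models)) NULL else models,
                 model_ids = ids,
                 org_pairs = org_pairs,
                 carb_pairs = carb_pairs,
                 oxygen_conditions = oxygen_conditions,
                 n_organisms = n_organisms, n_carbons = n_carbons,
                 base_metabolites = base_metabolites,
                 bound_policy = bound_policy),
            class = "sweep_plan")
}

#' Number of configurations in a sweep plan
#' @param plan a \code{sweep_plan}.
#' @return integer count (organism pairs x carbon pairs x oxygen states).
#' @export
n_configs <- function(plan) {
  stopifnot(inherits(plan, "sweep_plan"))
  ncol(plan$org_pairs) * ncol(plan$carb_pairs) *
    length(plan$oxygen_conditions)
}

#' Retrieve one configuration of a sweep plan by index
#' @param plan a \code{sweep_plan}.
#' @param k 1-based configuration index (column-major over organisms,
#'   carbons, oxygen).
#' @return list with \code{organisms}, \code{carbons}, \code{oxygen}.
#' @export
sweep_config <- function(plan, k) {
  n_o <- ncol(plan$org_pairs); n_c <- ncol(plan$carb_pairs)
  stopifnot(k >= 1, k <= n_configs(plan))
  k0 <- k - 1L
  i_o <- k0 %% n_o
  i_c <- (k0 %/% n_o) %% n_c
  i_x <- k0 %/% (n_o * n_c)
  list(organisms = plan$org_pairs[, i_o + 1L],
       carbons = plan$carb_pairs[, i_c + 1L],
       oxygen = plan$oxygen_conditions[i_x + 1L])
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("<sweep_plan> %d models x %d carbons x %s O2 -> %d configs\n",
              length(x$model_ids), nrow(x$carb_pairs) * 0 +
                length(unique(as.vector(x$carb_pairs))),
              paste(x$oxygen_conditions, collapse = "/"), n_configs(x)))
  invisible(x)
}

fmt_fluxset <- function(v) {
  if (!length(v)) return("")
  paste(sprintf("%s:%.6g", names(v), as.numeric(v)), collapse = ";")
}

#' Execute a sweep plan
#'
#' Runs every configuration through \code{\link{run_pair_experiment}} and
#' \code{\link{classify_interaction}}, producing one row per
#' configuration.  Output is checkpointed row-by-row to
#' \code{output_path} (TSV) and can be resumed after interruption; the
#' run is deterministic, so a resumed table equals an uninterrupted one.
#'
#' @param plan a \code{sweep_plan} carrying actual models.
#' @param output_path TSV checkpoint path, or \code{NULL} for in-memory
#'   only.
#' @param resume continue from an existing checkpoint file.
#' @param exclusion metabolites excluded from exchange-edge evidence, see
#'   \code{\link{classify_interaction}}.
#' @param defaults cutoffs, see \code{\link{fba_defaults}}.
#' @param progress log every \code{progress} configs (0 = silent).
#' @return data.frame of results (also written to \code{output_path}).
#' @export
run_sweep <- function(plan, output_path = NULL, resume = FALSE,
                      exclusion = c("h2o_e", "h_e"),
                      defaults = fba_defaults(), progress = 0L) {
  stopifnot(inherits(plan, "sweep_plan"))
  if (is.null(plan$models))
    stop("plan carries only model ids; rebuild it with actual models")
  if (plan$n_organisms != 2L)
    stop("execution supports pairwise plans (N_M = 2)")
  models <- plan$models
  names(models) <- plan$model_ids
  header <- c("org_i", "org_j", "carbon_a", "carbon_b", "o2_i", "o2_j",
              "grow_i", "grow_j", "solo_grow_i", "solo_grow_j", "c_s",
              "secreted_i", "secreted_j", "uptaken_i", "uptaken_j",
              "interaction", "motif")
  done <- 0L
  rows <- list()
  if (!is.null(output_path) && resume && file.exists(output_path)) {
    prev <- tryCatch(
      utils::read.delim(output_path, stringsAsFactors = FALSE,
                        colClasses = "character"),
      error = function(e)
        stop("corrupt checkpoint: ", conditionMessage(e)))
    if (!identical(names(prev), header))
      stop("corrupt checkpoint: header mismatch in ", output_path)
    done <- nrow(prev)
    if (done > n_configs(plan))
      stop("corrupt checkpoint: more rows than configs")
    rows <- lapply(seq_len(done), function(i) prev[i, ])
  } else if (!is.null(output_path)) {
    writeLines(paste(header, collapse = "\t"), output_path)
  }
  con <- if (!is.null(output_path)) file(output_path, "a") else NULL
  on.exit(if (!is.null(con)) close(con))
  total <- n_configs(plan)
  for (k in seq_len(total)) {
    if (k <= done) next
    cfg <- sweep_config(plan, k)
    med <- build_medium(plan$base_metabolites, cfg$carbons,
                        oxygen = cfg$oxygen,
                        bound_policy = plan$bound_policy)
    rec <- run_pair_experiment(models[[cfg$organisms[1]]],
                               models[[cfg$organisms[2]]],
                               med, cfg$oxygen, cfg$oxygen,
                               defaults = defaults)
    lab <- classify_interaction(rec, exclusion = exclusion,
                                defaults = defaults)
    fin <- rec$iterations[[rec$c_s]]
    row <- data.frame(
      org_i = cfg$organisms[1], org_j = cfg$organisms[2],
      carbon_a = cfg$carbons[1], carbon_b = cfg$carbons[2],
      o2_i = cfg$oxygen, o2_j = cfg$oxygen,
      grow_i = as.integer(fin$growth[1]),
      grow_j = as.integer(fin$growth[2]),
      solo_grow_i = as.integer(rec$solo_growth[1]),
      solo_grow_j = as.integer(rec$solo_growth[2]),
      c_s = rec$c_s,
      secreted_i = fmt_fluxset(fin$secretions[[1]]),
      secreted_j = fmt_fluxset(fin$secretions[[2]]),
      uptaken_i = fmt_fluxset(fin$uptakes[[1]]),
      uptaken_j = fmt_fluxset(fin$uptakes[[2]]),
      interaction = lab$status,
      motif = if (is.na(lab$motif_code)) "" else lab$motif_code,
      stringsAsFactors = FALSE)
    rows[[k]] <- row
    if (!is.null(con)) {
      writeLines(paste(vapply(row, as.character, character(1)),
                       collapse = "\t"), con)
      flush(con)
    }
    if (progress > 0L && k %% progress == 0L)
      message("sweep: ", k, "/", total)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(header)),
                 stringsAsFactors = FALSE), header)
  rownames(out) <- NULL
  for (col in c("grow_i", "grow_j", "solo_grow_i", "solo_grow_j", "c_s"))
    out[[col]] <- as.integer(out[[col]])
  out
}
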