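# Command-line entry point tying the modules together.  Subcommands
# mirror the analysis stages: gen-toy, run-pair, sweep, classify,
# coopindex, stability, report.  Every output directory receives a JSON
# config snapshot sufficient to reproduce the run.

parse_flags <- function(args) {
  flags <- list(); positional <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[[i + 1L]], "--")) {
        flags[[key]] <- args[[i + 1L]]; i <- i + 2L
      } else {
        flags[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      positional <- c(positional, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

flag_or <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else flags[[key]]
}

snapshot_config <- function(dir, subcommand, flags) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(tool = "crossfeed", version =
           as.character(utils::packageVersion("crossfeedr")),
         subcommand = subcommand, flags = flags,
         cutoffs = fba_defaults()),
    file.path(dir, "config_snapshot.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

load_models_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.(json|xml|sbml)$",
                      full.names = TRUE)
  models <- list()
  for (p in sort(paths)) {
    m <- tryCatch(read_model(p), error = function(e) NULL)
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  if (!length(models)) stop("no models found in ", dir)
  models
}

usage <- function() {
  cat("usage: crossfeed <subcommand> [flags]\n",
      "subcommands:\n",
      "  gen-toy   --suite N_ORG,N_CARBON --seed S --out DIR\n",
      "  run-pair  --models DIR --medium TSV --o2 present|absent[,..] --out DIR\n",
      "  sweep     --models DIR --carbons FILE --o2 both|present|absent --out DIR [--resume]\n",
      "  classify  --models DIR --medium TSV --o2 ... --out DIR\n",
      "  coopindex --gab N --ga N --gb N --nab N [--na N --nb N]\n",
      "  stability --motif CODE --grid N --out DIR [--params JSON]\n",
      "  report    --results TSV --out DIR\n", sep = "")
}

#' Command-line interface
#'
#' Dispatches the \code{crossfeed} subcommands (see the package README
#' for a worked tutorial).  Designed to be called from the installed
#' \code{crossfeed} script via
#' \code{Rscript -e 'crossfeedr::crossfeed_main()'}.
#'
#' @param argv character vector of command-line arguments; defaults to
#'   the process arguments.
#' @return integer exit status, invisibly (0 success, 2 usage error).
#' @export
crossfeed_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { usage(); return(invisible(2L)) }
  sub <- argv[[1]]
  pf <- parse_flags(argv[-1])
  flags <- pf$flags
  status <- tryCatch({
    switch(
      sub,
      "gen-toy" = {
        dims <- as.integer(strsplit(flag_or(flags, "suite", "4,6"),
                                    ",")[[1]])
        suite <- make_suite(dims[1], dims[2],
                            seed = as.integer(flag_or(flags, "seed", 1)))
        out <- flag_or(flags, "out", "toy_suite")
        write_suite(suite, out)
        snapshot_config(out, sub, flags)
        message("wrote ", length(suite$models), " models to ", out)
        0L
      },
      "run-pair" = ,
      "classify" = {
        models <- load_models_dir(flags$models)
        if (length(models) < 2) stop("need two models")
        o2 <- strsplit(flag_or(flags, "o2", "present"), ",")[[1]]
        if (length(o2) == 1L) o2 <- rep(o2, 2)
        med <- read_medium_tsv(flags$medium, oxygen = o2[1])
        rec <- run_pair_experiment(models[[1]], models[[2]], med,
                                   o2[1], o2[2])
        lab <- classify_interaction(rec)
        out <- flag_or(flags, "out", "pair_out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(
          list(organisms = rec$organisms, c_s = rec$c_s,
               growth = rec$iterations[[rec$c_s]]$growth,
               solo_growth = rec$solo_growth,
               interaction = lab$status, motif = lab$motif_code,
               obligate = as.list(obligate_syntrophy(rec)),
               exchange_edges = lab$exchange_edges),
          file.path(out, "pair_result.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        snapshot_config(out, sub, flags)
        message("motif: ", lab$motif_code, " (", lab$status, ")")
        0L
      },
      "sweep" = {
        models <- load_models_dir(flags$models)
        carbons <- readLines(flags$carbons)
        carbons <- carbons[nzchar(carbons)]
        o2 <- switch(flag_or(flags, "o2", "both"),
                     both = c("present", "absent"),
                     present = "present", absent = "absent",
                     stop("bad --o2"))
        plan <- plan_sweep(models, carbons, oxygen_conditions = o2)
        out <- flag_or(flags, "out", "sweep_out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        res <- run_sweep(plan, file.path(out, "results.tsv"),
                         resume = isTRUE(flags$resume) ||
                           identical(flags$resume, "true"))
        write_summary_tsvs(summarize_sweep(res), out)
        snapshot_config(out, sub, flags)
        message("sweep: ", nrow(res), " configs -> ", out)
        0L
      },
      "coopindex" = {
        val <- cooperativity_index(
          as.numeric(flags$gab), as.numeric(flags$ga),
          as.numeric(flags$gb), as.numeric(flags$nab),
          as.numeric(flag_or(flags, "na", flags$nab)),
          as.numeric(flag_or(flags, "nb", flags$nab)))
        cat(format(val, digits = 10), "\n")
        0L
      },
      "stability" = {
        params <- if (!is.null(flags$params)) {
          do.call(chemostat_params,
                  jsonlite::read_json(flags$params,
                                      simplifyVector = TRUE))
        } else chemostat_params()
        map <- stability_map(flags$motif, params,
                             grid_n = as.integer(flag_or(flags, "grid",
                                                         51)))
        out <- flag_or(flags, "out", "stability_out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_stability_map(map, file.path(out, paste0("stability_",
                                                       flags$motif)))
        snapshot_config(out, sub, flags)
        message("stable fraction: ", format(mean(map$stable)))
        0L
      },
      "report" = {
        res <- utils::read.delim(flags$results,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
        res$c_s <- as.integer(res$c_s)
        out <- flag_or(flags, "out", "report_out")
        write_summary_tsvs(summarize_sweep(res), out)
        snapshot_config(out, sub, flags)
        0L
      },
      { usage(); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
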