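#' Pipeline configuration
#'
#' One object drives the full analysis: either file inputs (PED/MAP or CSV
#' genotype table) or a simulation config, stage toggles, and the shared
#' statistical settings. A seed is mandatory whenever a stochastic stage
#' (simulation, MDR) is enabled.
#'
#' @param input optional list: `list(ped =, map =)` or `list(csv =)`.
#' @param simulate optional [cohort_config()]; used when `input` is `NULL`.
#' @param stages character subset of
#'   `c("assoc", "haplo", "ld", "mdr", "survival")`.
#' @param haplo_blocks list of SNP-id vectors defining haplotype blocks;
#'   defaults to the simulation blocks, or consecutive triples of the
#'   panel's SNPs.
#' @param alpha significance level carried into reports.
#' @param folds,k_range,n_perm MDR settings (see [mdr_search()]).
#' @param survival_snps SNP ids for genotype survival curves (default: all).
#' @param seed integer seed.
#' @param out_dir output directory for the report bundle (`NULL` = don't
#'   write).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            stages = c("assoc", "haplo", "ld", "mdr",
                                       "survival"),
                            haplo_blocks = NULL, alpha = 0.05, folds = 10L,
                            k_range = 1:2, n_perm = 1000L,
                            survival_snps = NULL, seed = NULL,
                            out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(input) && is.null(simulate))
    stop("either file input or a simulation config is required")
  if (!is.null(input)) {
    paths <- unlist(input)
    missing_f <- paths[!file.exists(paths)]
    if (length(missing_f))
      stop("input file(s) not found: ", paste(missing_f, collapse = ", "))
  }
  stochastic <- !is.null(simulate) || "mdr" %in% stages
  if (stochastic && is.null(seed) &&
      (is.null(simulate) || is.null(simulate$seed)))
    stop("a seed is mandatory when a stochastic stage is enabled")
  structure(list(input = input, simulate = simulate, stages = stages,
                 haplo_blocks = haplo_blocks, alpha = alpha,
                 folds = as.integer(folds), k_range = k_range,
                 n_perm = as.integer(n_perm), survival_snps = survival_snps,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL          # analysis identity, not output placement
  s <- utf8ToInt(yaml::as.yaml(x))
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% 2147483647)
}

load_pipeline_panel <- function(config) {
  if (!is.null(config$input)) {
    if (!is.null(config$input$ped))
      read_ped_map(config$input$ped, config$input$map)
    else read_genotype_table(config$input$csv)
  } else simulate_cohort(config$simulate,
                         seed = config$simulate$seed %||% config$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_haplo_blocks <- function(config, panel) {
  if (!is.null(config$haplo_blocks)) return(config$haplo_blocks)
  if (!is.null(config$simulate))
    return(lapply(config$simulate$blocks, function(b) b$snps$snp_id))
  ids <- panel$snps$snp_id
  split(ids, ceiling(seq_along(ids) / 3))[lengths(
    split(ids, ceiling(seq_along(ids) / 3))) >= 2]
}

run_stage <- function(name, out_dir, expr) {
  message("[snpcc] stage ", name, " ...")
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste0("FAILED at stage ", name, ": ",
                        conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — single-SNP association (HWE,
#' allelic and genotypic tables), haplotype estimation and association per
#' block, pairwise LD, the MDR interaction search with entropy analysis,
#' and genotype survival — on a panel read from files or freshly
#' simulated. Per-stage sample counts are logged; a failing stage aborts
#' the run with its name, leaving earlier outputs plus a `FAILED` marker.
#' Identical config and seed give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `meta` (seed, config hash,
#'   counts) plus one element per executed stage; written to
#'   `config$out_dir` as TSVs + JSON when set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(meta = list(config_hash = config_hash(config),
                          seed = config$seed %||% config$simulate$seed,
                          stages = config$stages))
  tables <- list()
  panel <- run_stage("load", config$out_dir, load_pipeline_panel(config))
  out$meta$n_cases <- n_cases(panel)
  out$meta$n_controls <- n_controls(panel)
  out$meta$n_snps <- n_snps(panel)
  message("[snpcc] panel: ", n_cases(panel), " cases / ",
          n_controls(panel), " controls, ", n_snps(panel), " SNPs")

  if ("assoc" %in% config$stages) {
    res <- run_stage("assoc", config$out_dir, {
      list(hwe = rbind(hwe_screen(panel, "control", config$alpha),
                       hwe_screen(panel, "case", config$alpha)),
           allelic = allelic_association(panel),
           genotypic = genotypic_association(panel, "pairwise"),
           dominant = genotypic_association(panel, "dominant"))
    })
    out$assoc <- res
    tables$hwe <- res$hwe
    tables$association <- res$allelic
    tables$genotypic <- rbind(res$genotypic, res$dominant)
  }

  blocks <- default_haplo_blocks(config, panel)
  if ("haplo" %in% config$stages) {
    res <- run_stage("haplo", config$out_dir, {
      rows <- lapply(seq_along(blocks), function(i) {
        h <- haplotype_association(panel, blocks[[i]])
        cbind(block = paste(blocks[[i]], collapse = ","), h)
      })
      do.call(rbind, rows)
    })
    out$haplotypes <- res
    tables$haplotypes <- res
  }

  if ("ld" %in% config$stages) {
    res <- run_stage("ld", config$out_dir, ld_matrix(panel))
    out$ld <- res
    tables$ld <- res
  }

  if ("mdr" %in% config$stages) {
    res <- run_stage("mdr", config$out_dir, {
      search <- mdr_search(panel, k_range = config$k_range,
                           folds = config$folds, seed = config$seed %||% 1L,
                           n_perm = config$n_perm)
      ent <- entropy_analysis(panel)
      list(search = search, entropy = ent)
    })
    out$mdr <- res
    tables$mdr_models <- res$search$summary
    tables$entropy_main <- data.frame(snp_id = names(res$entropy$main_ig),
                                      ig_pct = unname(res$entropy$main_ig))
    tables$entropy_pairs <- res$entropy$pair_ig
    out$meta$mdr_best <- paste(res$search$best$combo, collapse = ",")
  }

  if ("survival" %in% config$stages && !is.null(panel$time)) {
    snps <- config$survival_snps %||% panel$snps$snp_id
    res <- run_stage("survival", config$out_dir, {
      lapply(stats::setNames(nm = snps), function(s)
        tryCatch(survival_by_genotype(panel, s),
                 error = function(e) conditionMessage(e)))
    })
    out$survival <- res
    rows <- lapply(names(res), function(s) {
      r <- res[[s]]
      if (is.character(r))
        return(data.frame(snp_id = s, group = NA, time = NA_real_,
                          survival = NA_real_, at_risk = NA_integer_,
                          note = r))
      do.call(rbind, lapply(names(r$curves), function(g) {
        k <- r$curves[[g]]
        if (!length(k$times))
          return(data.frame(snp_id = s, group = g, time = NA_real_,
                            survival = 1, at_risk = k$n, note = "no events"))
        data.frame(snp_id = s, group = g, time = k$times,
                   survival = k$survival, at_risk = k$at_risk, note = "")
      }))
    })
    tables$survival <- do.call(rbind, rows)
    tables$logrank <- do.call(rbind, lapply(names(res), function(s) {
      r <- res[[s]]
      if (is.character(r) || is.null(r$test))
        data.frame(snp_id = s, chi2 = NA_real_, df = NA_integer_,
                   p = NA_real_)
      else data.frame(snp_id = s, chi2 = r$test$chi2, df = r$test$df,
                      p = r$test$p)
    }))
  }

  out$tables <- tables
  if (!is.null(config$out_dir))
    write_report(tables, config$out_dir, meta = out$meta)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages: ", paste(x$meta$stages, collapse = ", "),
      " | ", x$meta$n_cases, " cases / ", x$meta$n_controls, " controls, ",
      x$meta$n_snps, " SNPs | config ", x$meta$config_hash, "\n", sep = "")
  if (!is.null(x$meta$mdr_best))
    cat("  MDR best model: ", x$meta$mdr_best, "\n", sep = "")
  invisible(x)
}

#' Simulate a cohort and write it to files
#'
#' Writes PED/MAP, a phenotype/genotype CSV, and the truth record (the
#' generating config as YAML) so downstream recovery tests can compare
#' estimates with the generating parameters.
#'
#' @param config a [cohort_config()] (its `seed` must be set).
#' @param out_dir output directory.
#' @return Invisibly, the written paths.
#' @export
simulate_cohort_files <- function(config, out_dir) {
  if (is.null(config$seed))
    stop("config error: field 'seed' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_cohort(config)
  paths <- c(
    write_ped_map(panel, file.path(out_dir, "cohort.ped"),
                  file.path(out_dir, "cohort.map")),
    csv = write_genotype_table(panel, file.path(out_dir, "cohort.csv")),
    truth = write_cohort_config(config, file.path(out_dir, "truth.yaml")))
  invisible(paths)
}
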