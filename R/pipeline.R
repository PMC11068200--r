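# End-to-end orchestration: score spectra, extract per-site properties from
# structures, assemble the per-site records table and run the statistical
# layer (per-class NB regression, categorical tests, eCDF summaries).

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: matching tolerance 5 m/z,
#' RIN contact threshold 7 Angstrom (sequence separation >= 1), pLDDT
#' exclusion cutoff 70, hydrogen-bond window 2.5-3.2 Angstrom, salt-bridge
#' cutoff 4.0 Angstrom, and the score threshold 10 used for the eCDF tail
#' summary.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    protein_table = NULL,
    tol = 5,
    rin_threshold = 7,
    min_sep = 1L,
    plddt_cutoff = 70,
    hbond_range = c(2.5, 3.2),
    salt_bridge_cutoff = 4.0,
    score_threshold = 10,
    outdir = NULL,
    seed = NULL
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$tol > 0, cfg$rin_threshold > 0,
            cfg$salt_bridge_cutoff > 0, all(cfg$hbond_range > 0))
  cfg
}

#' Read a pipeline configuration from a key = value text file
#'
#' Unknown keys are an error; \code{hbond_range} is given as two
#' comma-separated numbers. Lines starting with \code{#} are ignored.
#'
#' @param path Path to the config file.
#' @return Configuration list as from \code{\link{default_config}}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  over <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(p[2])
    over[[key]] <- switch(key,
      protein_table = , outdir = val,
      hbond_range = as.numeric(strsplit(val, ",")[[1]]),
      min_sep = , seed = as.integer(val),
      as.numeric(val))
  }
  do.call(default_config, over)
}

#' Extract the per-site property vector from a structure
#'
#' For each requested residue position, computes the structural descriptors
#' (backbone/side-chain hydrogen-bond counts, salt-bridge presence,
#' 8-state secondary structure, relative solvent accessibility) and the
#' eight RIN centralities.
#'
#' @param struct A \code{psd_structure}.
#' @param positions Residue indices (the D/E/N cleavage sites).
#' @param config Configuration list (see \code{\link{default_config}}).
#' @return data.frame with one row per position: \code{position},
#'   numeric properties (\code{degree}, \code{strength}, \code{clustering},
#'   \code{closeness}, \code{betweenness}, \code{eigenvector},
#'   \code{eccentricity}, \code{annd}, \code{backbone_hbond_count},
#'   \code{sidechain_hbond_count}, \code{rsa}) and categoricals
#'   (\code{secondary_structure}, \code{salt_bridge}).
#' @export
extract_site_properties <- function(struct, positions,
                                    config = default_config()) {
  graph <- build_rin(struct, threshold = config$rin_threshold,
                     min_sep = config$min_sep)
  cent <- rin_centralities(graph)
  ss <- assign_secondary_structure(struct)
  rsa <- suppressWarnings(relative_solvent_accessibility(struct))
  hb <- t(vapply(positions, function(p)
    count_hbonds(struct, p, config$hbond_range), integer(2)))
  sb <- vapply(positions, function(p)
    has_salt_bridge(struct, p, config$salt_bridge_cutoff), logical(1))
  ci <- match(positions, cent$residue_index)
  data.frame(
    position = positions,
    cent[ci, c("degree", "strength", "clustering", "closeness",
               "betweenness", "eigenvector", "eccentricity", "annd")],
    backbone_hbond_count = hb[, 1],
    sidechain_hbond_count = hb[, 2],
    rsa = unname(rsa[as.character(positions)]),
    secondary_structure = unname(ss[as.character(positions)]),
    salt_bridge = sb,
    row.names = NULL
  )
}

.numeric_properties <- c(
  "degree", "backbone_hbond_count", "sidechain_hbond_count", "rsa",
  "clustering", "closeness", "betweenness", "eigenvector", "annd",
  "eccentricity"
)
.categorical_properties <- c(
  "secondary_structure", "nterm_neighbor", "cterm_neighbor", "salt_bridge"
)

#' Run the full fragmentation-efficiency analysis
#'
#' Executes the study workflow over a protein table: per-protein fragment
#' prediction and signal scoring; pLDDT filtering; per-site structural and
#' network properties for retained proteins; per-residue-class (D/E/N)
#' negative-binomial regression of signal scores on the 0-1-scaled numeric
#' properties (strength removed by the cross-correlation screen, scores
#' rounded to integers for the regression only); Kruskal-Wallis and pairwise
#' Mann-Whitney tests of the categorical properties; and eCDF summaries
#' (fraction of scores above the threshold per class, E/N eCDF Pearson r).
#'
#' @param config Configuration list from \code{\link{default_config}} or
#'   \code{\link{read_run_config}}. \code{protein_table} must be a
#'   data.frame or TSV path with columns \code{protein_id},
#'   \code{sequence}, \code{spectrum_path}, \code{structure_path},
#'   \code{precursor_mz} (structure path may be NA).
#' @return List of class \code{psd_pipeline_result}: \code{records}
#'   (per-site table), \code{regression} (per-class coefficient tables and
#'   LRT p), \code{categorical} (per-class Kruskal-Wallis p),
#'   \code{pairwise} (per class/property Mann-Whitney p matrices),
#'   \code{ecdf_summary}, \code{excluded_proteins}, \code{log}.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tab <- config$protein_table
  if (is.character(tab))
    tab <- utils::read.delim(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "sequence", "spectrum_path") %in% names(tab)))
  if (is.null(tab$structure_path)) tab$structure_path <- NA_character_
  if (is.null(tab$precursor_mz)) tab$precursor_mz <- NA_real_

  log <- list()
  records <- list()
  excluded <- character(0)
  for (k in seq_len(nrow(tab))) {
    id <- tab$protein_id[k]
    scored <- tryCatch({
      spec <- read_centroid_spectrum(tab$spectrum_path[k])
      pm <- tab$precursor_mz[k]
      score_protein(tab$sequence[k], spec, id,
                    precursor_mz = if (is.na(pm)) NULL else pm,
                    tol = config$tol)
    }, error = function(e)
      stop("stage scoring failed for protein '", id, "': ",
           conditionMessage(e)))
    has_struct <- !is.na(tab$structure_path[k]) &&
      nzchar(tab$structure_path[k])
    if (has_struct) {
      props <- tryCatch({
        struct <- read_structure(tab$structure_path[k])
        if (mean_plddt(struct) < config$plddt_cutoff) {
          excluded <- c(excluded, id)
          NULL
        } else {
          extract_site_properties(struct, scored$position, config)
        }
      }, error = function(e)
        stop("stage structure_props failed for protein '", id, "': ",
             conditionMessage(e)))
    } else props <- NULL
    if (is.null(props)) {
      props <- data.frame(position = scored$position)
      for (v in c(.numeric_properties, "strength")) props[[v]] <- NA_real_
      props$secondary_structure <- NA_character_
      props$salt_bridge <- NA
    }
    records[[k]] <- merge(scored, props, by = "position", sort = TRUE)
  }
  records <- do.call(rbind, records)
  records <- records[order(records$protein_id, records$position), ]
  rownames(records) <- NULL
  log$n_proteins <- nrow(tab)
  log$n_excluded_plddt <- length(excluded)
  log$n_sites <- nrow(records)
  log$n_sites_matched <- sum(records$u > 0)
  log$params <- config[c("tol", "rin_threshold", "min_sep", "plddt_cutoff",
                         "hbond_range", "salt_bridge_cutoff",
                         "score_threshold")]

  regression <- list()
  categorical <- list()
  pairwise <- list()
  for (cls in c("D", "E", "N")) {
    sub <- records[records$residue == cls, , drop = FALSE]
    # regression on structure-retained sites only
    xs <- sub[!is.na(sub$degree), , drop = FALSE]
    regression[[cls]] <- .fit_class_regression(xs)
    categorical[[cls]] <- .categorical_tests(sub)
    pairwise[[cls]] <- .pairwise_tests(sub)
  }
  ecdf_summary <- .ecdf_summary(records, config$score_threshold)

  out <- structure(list(
    records = records, regression = regression,
    categorical = categorical, pairwise = pairwise,
    ecdf_summary = ecdf_summary, excluded_proteins = excluded,
    log = log
  ), class = "psd_pipeline_result")
  if (!is.null(config$outdir)) .write_results(out, config$outdir)
  out
}

.fit_class_regression <- function(xs) {
  if (nrow(xs) < 30L)
    return(list(table = NULL, lrt_p = NA_real_, dropped = character(0),
                n = nrow(xs)))
  Xall <- xs[, c("degree", "strength", .numeric_properties[-1]),
             drop = FALSE]
  Xall <- Xall[, vapply(Xall, function(v) stats::sd(v) > 0, logical(1)),
               drop = FALSE]
  scr <- cross_correlation_screen(Xall)
  X <- as.data.frame(lapply(seq_along(scr$X), function(j)
    minmax_scale(scr$X[[j]], names(scr$X)[j])))
  names(X) <- names(scr$X)
  fit <- fit_negative_binomial(X, round(xs$score))
  list(table = data.frame(
         variable = names(fit$coefficients),
         estimate = unname(fit$coefficients),
         std_error = unname(fit$standard_errors),
         p_value = unname(fit$p_values)),
       lrt_p = fit$lrt_p, dispersion = fit$dispersion,
       dropped = scr$dropped, n = nrow(xs), fit = fit)
}

.categorical_tests <- function(sub) {
  out <- data.frame(property = .categorical_properties,
                    p_value = NA_real_, n_groups = NA_integer_)
  for (i in seq_along(.categorical_properties)) {
    v <- .categorical_properties[i]
    ok <- !is.na(sub[[v]]) & !is.na(sub$score)
    g <- split(sub$score[ok], as.character(sub[[v]][ok]))
    g <- g[lengths(g) >= 1L]
    out$n_groups[i] <- length(g)
    if (length(g) >= 2L)
      out$p_value[i] <- kruskal_wallis(g)$p
  }
  out
}

.pairwise_tests <- function(sub) {
  res <- list()
  for (v in .categorical_properties) {
    ok <- !is.na(sub[[v]]) & !is.na(sub$score)
    g <- split(sub$score[ok], as.character(sub[[v]][ok]))
    g <- g[lengths(g) >= 1L]
    if (length(g) >= 2L) res[[v]] <- mann_whitney_pairwise(g)
  }
  res
}

.ecdf_summary <- function(records, threshold) {
  by_class <- split(records$score, records$residue)
  frac <- vapply(c("D", "E", "N"), function(cl) {
    s <- by_class[[cl]]
    if (is.null(s) || length(s) == 0L) return(NA_real_)
    mean(s > threshold)
  }, numeric(1))
  r_en <- if (!is.null(by_class$E) && !is.null(by_class$N) &&
              length(by_class$E) >= 2L && length(by_class$N) >= 2L)
    ecdf_correlation(by_class$E, by_class$N) else NA_real_
  list(frac_above_threshold = frac, threshold = threshold,
       ecdf_pearson_e_n = r_en)
}

.write_results <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$records, file.path(outdir, "site_records.tsv"))
  for (cls in names(result$regression)) {
    reg <- result$regression[[cls]]
    if (!is.null(reg$table)) {
      tab <- reg$table
      tab$lrt_p <- reg$lrt_p
      write_tsv(tab, file.path(outdir,
                               sprintf("regression_%s.tsv", cls)))
    }
    write_tsv(result$categorical[[cls]],
              file.path(outdir, sprintf("categorical_%s.tsv", cls)))
  }
  es <- result$ecdf_summary
  write_tsv(data.frame(class = names(es$frac_above_threshold),
                       frac_above = unname(es$frac_above_threshold),
                       threshold = es$threshold,
                       ecdf_pearson_e_n = es$ecdf_pearson_e_n),
            file.path(outdir, "ecdf_summary.tsv"))
  lg <- result$log
  writeLines(c(
    sprintf("proteins: %d", lg$n_proteins),
    sprintf("excluded_plddt: %d (%s)", lg$n_excluded_plddt,
            paste(result$excluded_proteins, collapse = ", ")),
    sprintf("sites: %d", lg$n_sites),
    sprintf("sites_with_signal: %d", lg$n_sites_matched),
    sprintf("params: %s", paste(names(lg$params),
                                vapply(lg$params, function(p)
                                  paste(p, collapse = "-"), ""),
                                sep = "=", collapse = " "))
  ), file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.psd_pipeline_result <- function(x, ...) {
  cat("PSD fragmentation-efficiency analysis\n")
  cat(sprintf("  proteins: %d (%d excluded by pLDDT filter)\n",
              x$log$n_proteins, x$log$n_excluded_plddt))
  cat(sprintf("  cleavage sites: %d (%d with matched signal)\n",
              x$log$n_sites, x$log$n_sites_matched))
  f <- x$ecdf_summary$frac_above_threshold
  cat(sprintf("  score > %g: D %.1f%%, E %.1f%%, N %.1f%%\n",
              x$ecdf_summary$threshold, 100 * f["D"], 100 * f["E"],
              100 * f["N"]))
  cat(sprintf("  E/N eCDF Pearson r: %.3f\n",
              x$ecdf_summary$ecdf_pearson_e_n))
  for (cls in names(x$regression)) {
    reg <- x$regression[[cls]]
    if (is.null(reg$table)) next
    sig <- reg$table$variable[reg$table$p_value < 0.05 &
                              reg$table$variable != "(Intercept)"]
    cat(sprintf("  %s regression (n=%d, LRT p=%.2g): significant: %s\n",
                cls, reg$n, reg$lrt_p,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}
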