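## Run configuration and the two assembled analyses: boundary meta-profiles
## (scnRNA and ChIP/input) and BBI tables / boxplot summaries / top-N
## heatmaps. Every figure's numbers are written as TSV first; outputs embed
## the full parameter set and input checksums, and reruns with identical
## inputs are byte-identical (no timestamps).

.cfgDefaults <- list(
  window = 500, meta_bin = 10, locus_bin = 100, heatmap_bin = 50,
  anchor_locus = "five_prime", anchor_meta = "nt13",
  anchor_chip = "midpoint", pseudocount = 1, min_control_reads = 10,
  top_n = 50, per_ies = FALSE, exclude_foreign = FALSE, plots = TRUE,
  seed = 1, reference = NULL)

#' Read and validate a run configuration
#'
#' YAML with `annotation` (BED), `chrom_lengths` (TSV), `out_dir`, a
#' `libraries` list of `{path, name, role}` entries (roles
#' `scnrna_sample`, `scnrna_control`, `chip`, `input`) and optional
#' overrides of the defaults (`window` 500, `meta_bin` 10, `locus_bin` 100,
#' `heatmap_bin` 50, anchors, `pseudocount` 1, `min_control_reads` 10,
#' `top_n` 50, `per_ies`, `exclude_foreign`, `plots`, `seed`, `reference`).
#' Relative paths are resolved against the YAML's directory.
#'
#' @param path YAML config path.
#' @return The validated config list (class `RunConfig`).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  cfg$annotation <- rel(cfg$annotation)
  cfg$chrom_lengths <- rel(cfg$chrom_lengths)
  if (!is.null(cfg$out_dir)) cfg$out_dir <- rel(cfg$out_dir)
  cfg$libraries <- lapply(cfg$libraries, function(l) {
    l$path <- rel(l$path); l
  })
  validateRunConfig(cfg)
}

#' @describeIn readRunConfig validate a config assembled in R.
#' @param cfg a config list.
#' @export
validateRunConfig <- function(cfg) {
  for (k in names(.cfgDefaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- .cfgDefaults[[k]]
  for (k in c("annotation", "chrom_lengths", "out_dir"))
    if (is.null(cfg[[k]])) stop("config error: missing '", k, "'")
  if (is.null(cfg$libraries) || !length(cfg$libraries))
    stop("config error: no libraries declared")
  roles <- vapply(cfg$libraries, `[[`, "", "role")
  ok <- c("scnrna_sample", "scnrna_control", "chip", "input")
  if (!all(roles %in% ok))
    stop("config error: unknown role(s) ",
         paste(setdiff(roles, ok), collapse = ", "))
  for (b in c("meta_bin", "locus_bin", "heatmap_bin"))
    if (cfg$window %% cfg[[b]] != 0)
      stop("config error: ", b, " must divide the window width")
  structure(cfg, class = "RunConfig")
}

.libsByRole <- function(cfg, role) {
  sel <- Filter(function(l) l$role == role, cfg$libraries)
  lapply(sel, function(l) {
    filt <- role %in% c("scnrna_sample", "scnrna_control")
    scnLibrary(l$path, minLen = if (filt) 26 else NULL,
               maxLen = if (filt) 32 else NULL, name = l$name)
  })
}

.writeTsv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(params),
                     vapply(params, function(v) paste(format(v), collapse = ","),
                            character(1))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.paramHeader <- function(cfg, extra = list()) {
  c(list(coordinates = "0-based half-open (BED)", window = cfg$window,
         pseudocount = cfg$pseudocount,
         min_control_reads = cfg$min_control_reads, seed = cfg$seed),
    extra)
}

.inputChecksums <- function(cfg) {
  paths <- c(cfg$annotation, cfg$chrom_lengths,
             vapply(cfg$libraries, `[[`, "", "path"))
  as.list(tools::md5sum(paths))
}

#' Run the boundary meta-profile analysis
#'
#' For every scnRNA library writes type-A and type-B boundary meta-profile
#' TSVs (10-bp bins, 13th-nt anchor, columns `offset_bin`, `sense`,
#' `antisense`, `n_boundaries`); for a declared chip+input pair writes
#' input-normalized ratio meta-profiles (masked bins as `NA`). A manifest
#' JSON records all parameters, library totals, masked-bin counts and input
#' checksums. PDFs of each profile are written when `plots` is on.
#'
#' @param cfg a run config from [readRunConfig()] or [validateRunConfig()].
#' @return Invisibly, a list with the genome, profiles and output paths.
#' @export
runMeta <- function(cfg) {
  cfg <- validateRunConfig(unclass(cfg))
  roles <- vapply(cfg$libraries, `[[`, "", "role")
  if (xor("chip" %in% roles, "input" %in% roles))
    stop("config error: chip and input roles must be declared together")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- loadSegmentation(cfg$annotation, cfg$chrom_lengths)
  scn <- c(.libsByRole(cfg, "scnrna_sample"), .libsByRole(cfg, "scnrna_control"))
  outs <- list(); manifest <- list()
  profiles <- list()
  for (lib in scn) {
    for (ty in c("A", "B")) {
      mp <- metaProfile(lib, genome, ty, cfg$meta_bin, cfg$window,
                        cfg$anchor_meta, cfg$exclude_foreign)
      f <- file.path(cfg$out_dir, sprintf("meta_%s_type%s.tsv", lib@name, ty))
      .writeTsv(as.data.frame(mp), f, .paramHeader(cfg, list(
        library = lib@name, ies_type = ty, bin = cfg$meta_bin,
        anchor = cfg$anchor_meta, total_filtered = totalFiltered(lib))))
      outs[[basename(f)]] <- f
      profiles[[sprintf("%s_type%s", lib@name, ty)]] <- mp
      if (isTRUE(cfg$plots)) {
        pf <- sub("\\.tsv$", ".pdf", f)
        grDevices::pdf(pf, width = 6, height = 4)
        plotMetaProfile(mp, sprintf("%s, type-%s boundaries", lib@name, ty))
        grDevices::dev.off()
      }
    }
    manifest$libraries[[lib@name]] <- list(
      total_filtered = totalFiltered(lib), rpm_factor = rpmFactor(lib))
  }
  if ("chip" %in% roles) {
    pair <- chipPair(.libsByRole(cfg, "chip")[[1L]],
                     .libsByRole(cfg, "input")[[1L]])
    for (ty in c("A", "B")) {
      cr <- chipRatio(pair, genome = genome, iesType = ty,
                      binSize = cfg$meta_bin, window = cfg$window,
                      anchorMode = cfg$anchor_chip,
                      excludeForeign = cfg$exclude_foreign)
      f <- file.path(cfg$out_dir,
                     sprintf("chipratio_%s_type%s.tsv", pair@chip@name, ty))
      .writeTsv(as.data.frame(cr), f, .paramHeader(cfg, list(
        chip = pair@chip@name, input = pair@input@name, ies_type = ty,
        anchor = cfg$anchor_chip)))
      outs[[basename(f)]] <- f
      profiles[[sprintf("chipratio_type%s", ty)]] <- cr
      manifest$masked_bins[[sprintf("type%s", ty)]] <- cr@params$masked_bins
      if (isTRUE(cfg$plots)) {
        pf <- sub("\\.tsv$", ".pdf", f)
        grDevices::pdf(pf, width = 6, height = 4)
        plotMetaProfile(cr, sprintf("%s / %s, type-%s boundaries",
                                    pair@chip@name, pair@input@name, ty))
        grDevices::dev.off()
      }
    }
  }
  manifest$params <- .paramHeader(cfg, list(
    meta_bin = cfg$meta_bin, anchor_meta = cfg$anchor_meta,
    anchor_chip = cfg$anchor_chip, exclude_foreign = cfg$exclude_foreign))
  manifest$input_md5 <- .inputChecksums(cfg)
  mf <- file.path(cfg$out_dir, "manifest_meta.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(genome = genome, profiles = profiles,
                 outputs = c(outs, manifest = mf)))
}

#' Run the BBI analysis
#'
#' Computes the broken boundary index of every eligible boundary for each
#' `scnrna_sample` library against the designated `scnrna_control` library
#' (never inferred), writing per-strain BBI TSVs, a distribution-summary
#' JSON (n, median, quartiles per strain, the numbers behind the boxplot),
#' a boxplot PDF, and top-N heatmap TSVs (+PDFs) in which the rows are the
#' `top_n` highest-BBI boundaries of the reference strain (`cfg$reference`,
#' default the first sample) profiled in every library.
#'
#' @inheritParams runMeta
#' @return Invisibly, a list with the BBI tables, summaries and heatmaps.
#' @export
runBbi <- function(cfg) {
  cfg <- validateRunConfig(unclass(cfg))
  roles <- vapply(cfg$libraries, `[[`, "", "role")
  if (!"scnrna_sample" %in% roles)
    stop("config error: BBI needs at least one scnrna_sample library")
  if (sum(roles == "scnrna_control") != 1L)
    stop("config error: BBI needs exactly one scnrna_control library")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- loadSegmentation(cfg$annotation, cfg$chrom_lengths)
  samples <- .libsByRole(cfg, "scnrna_sample")
  control <- .libsByRole(cfg, "scnrna_control")[[1L]]
  names(samples) <- vapply(samples, libraryName, "")

  tables <- list(); summaries <- list(); outs <- list()
  for (lib in samples) {
    tbl <- bbiTable(lib, control, genome, cfg$window, cfg$pseudocount,
                    cfg$min_control_reads, cfg$anchor_meta,
                    cfg$exclude_foreign)
    f <- file.path(cfg$out_dir, sprintf("bbi_%s.tsv", lib@name))
    .writeTsv(tbl, f, .paramHeader(cfg, list(
      sample = lib@name, control = control@name,
      anchor = cfg$anchor_meta)))
    tables[[lib@name]] <- tbl
    summaries[[lib@name]] <- bbiSummary(tbl)
    outs[[basename(f)]] <- f
  }
  sf <- file.path(cfg$out_dir, "bbi_summary.json")
  jsonlite::write_json(list(params = .paramHeader(cfg),
                            control = control@name,
                            strains = summaries,
                            input_md5 = .inputChecksums(cfg)),
                       sf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(cfg$plots)) {
    bp <- file.path(cfg$out_dir, "bbi_boxplot.pdf")
    grDevices::pdf(bp, width = 2 + length(tables), height = 5)
    graphics::boxplot(lapply(tables, function(t) t$bbi[t$eligible]),
                      log = "y", ylab = "broken boundary index",
                      las = 2)
    graphics::abline(h = 1, lty = 3)
    grDevices::dev.off()
  }

  ref <- if (is.null(cfg$reference)) names(samples)[1L] else cfg$reference
  if (!ref %in% names(tables))
    stop("config error: reference strain '", ref, "' is not a sample")
  allLibs <- c(samples, stats::setNames(list(control), control@name))
  heat <- topNHeatmap(tables[[ref]], allLibs, genome, cfg$top_n,
                      cfg$heatmap_bin, cfg$window, cfg$anchor_meta,
                      cfg$per_ies)
  for (nm in names(heat)) {
    f <- file.path(cfg$out_dir, sprintf("heatmap_%s.tsv", nm))
    writeHeatmap(heat[[nm]], f,
                 pdfPath = if (isTRUE(cfg$plots)) sub("\\.tsv$", ".pdf", f),
                 strain = nm)
    outs[[basename(f)]] <- f
  }
  invisible(list(genome = genome, tables = tables, summaries = summaries,
                 heatmaps = heat, reference = ref, outputs = outs))
}
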