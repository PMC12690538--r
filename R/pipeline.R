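#' Build a validated pipeline configuration
#'
#' Collects every stage parameter, the per-library inputs and the genotype
#' grouping into one serializable object. Unknown fields are rejected.
#'
#' @param libraries Tibble or data frame with columns `library` (label),
#'   `fastq` (raw FASTQ path) and `group` (genotype label).
#' @param transposon_fasta,infra_fasta,hp_fasta Reference FASTA paths.
#' @param out_dir Output directory for all stage intermediates.
#' @param reference_group Genotype group used as the fold-change and linkage
#'   reference (default `"wildtype"`).
#' @param adapter,umi_len,min_len,max_len Preprocessing parameters.
#' @param infra_max_mm,sirna_range,pirna_min_len Classification parameters.
#' @param te_max_mm,fractional Transposon alignment parameters.
#' @param min_pairs,min_windows,eps,window_up,window_down Statistic
#'   parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(libraries,
                            transposon_fasta, infra_fasta, hp_fasta,
                            out_dir,
                            reference_group = "wildtype",
                            adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                            umi_len = 4L, min_len = 18L, max_len = 40L,
                            infra_max_mm = 1L,
                            sirna_range = c(20L, 22L),
                            pirna_min_len = 23L,
                            te_max_mm = 3L, fractional = FALSE,
                            min_pairs = 100, min_windows = 100L,
                            eps = 1, window_up = 10L, window_down = 1L) {
  libraries <- as_tibble(libraries)
  need <- c("library", "fastq", "group")
  if (!all(need %in% names(libraries))) {
    abort(paste("`libraries` must have columns:", paste(need, collapse = ", ")),
          class = "pirnakit_bad_config")
  }
  cfg <- mget(setdiff(names(formals()), "libraries"))
  cfg$libraries <- libraries
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are [pipeline_config()] arguments; any
#'   unknown key is an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste("Unknown configuration keys:", paste(unknown, collapse = ", ")),
          class = "pirnakit_bad_config")
  }
  do.call(pipeline_config, x)
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes, per library and in order: adapter/UMI preprocessing, size
#' selection, infrastructural filtering, endogenous-siRNA extraction, piRNA
#' definition, transposon alignment, siRNA-normalised abundance, the
#' ping-pong overlap spectrum and linkage z-scores, and the 3'-end +1U
#' signature. Replicates are averaged on the normalised scale per genotype
#' group; fold-change tables are written for every non-reference group, and a
#' ping-pong linkage comparison against the reference group is written
#' whenever at least three transposons have defined linkage in both groups.
#' Every stage intermediate is written to `out_dir`; a rerun with identical
#' config and inputs reproduces byte-identical tables.
#'
#' An empty input FASTQ yields all-zero tables with warnings (the abundance
#' column is `NA` when the library has no endogenous siRNAs to normalise by).
#'
#' @param config A [pipeline_config()] or a path to its JSON serialisation.
#' @return A manifest tibble (`artifact`, `library`, `file`, `md5`),
#'   invisibly the same as written to `manifest.json` together with input
#'   hashes and parameters.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  te <- read_fasta(config$transposon_fasta, class = "transposon")
  infra <- read_fasta(config$infra_fasta, class = "infrastructural")
  hp <- read_fasta(config$hp_fasta, class = "hpRNA")

  manifest <- list()
  emit <- function(artifact, library, data, file) {
    path <- file.path(config$out_dir, file)
    readr::write_tsv(data, path)
    manifest[[length(manifest) + 1]] <<- tibble(
      artifact = artifact, library = library, file = file,
      md5 = unname(tools::md5sum(path)))
    path
  }

  per_lib <- purrr::pmap(config$libraries[c("library", "fastq", "group")],
                         function(library, fastq, group) {
    pp <- preprocess_reads(fastq, adapter = config$adapter,
                           umi_len = config$umi_len,
                           lo = config$min_len, hi = config$max_len)
    emit("length_histogram", library, pp$histogram,
         paste0(library, "_lengths.tsv"))

    fi <- filter_infrastructural(pp$reads, infra, config$infra_max_mm)
    si <- extract_sirnas(fi$reads, hp, config$sirna_range,
                         config$infra_max_mm)
    pi <- define_pirnas(si$reads, config$pirna_min_len)
    log_tbl <- tibble(
      stage = c(names(pp$counts), "infrastructural", "sirna",
                "pirna_candidate", "unassigned"),
      n = c(unname(pp$counts), nrow(fi$removed), si$sirna_count,
            nrow(pi$pirna_candidates), nrow(pi$unassigned)))
    emit("read_accounting", library, log_tbl, paste0(library, "_counts.tsv"))

    aln <- align_reads(pi$pirna_candidates, te, max_mm = config$te_max_mm,
                       fractional = config$fractional)
    counts <- count_pirnas(aln, min_len = config$pirna_min_len,
                           universe = te$name)
    ab <- if (si$sirna_count > 0) {
      normalize_abundance(counts, si$sirna_count, library = library)
    } else {
      warn(sprintf("Library %s has no endogenous siRNAs; abundances are NA.",
                   library))
      mutate(counts, library = library, sirna_count = 0L,
             abundance = NA_real_) |>
        select("library", "transposon", "strand", "count", "sirna_count",
               "abundance")
    }
    emit("abundance", library, ab, paste0(library, "_abundance.tsv"))

    spec <- overlap_spectrum(aln, min_len = config$pirna_min_len)
    emit("overlap_spectrum", library, spec, paste0(library, "_spectrum.tsv"))
    lz <- linkage_z(spec, min_pairs = config$min_pairs)
    emit("linkage", library, lz, paste0(library, "_linkage.tsv"))

    win <- collect_windows(aln, te, window_up = config$window_up,
                           window_down = config$window_down,
                           min_len = config$pirna_min_len)
    sig <- end_signature(win$windows, min_windows = config$min_windows,
                         window_down = config$window_down)
    sig_tbl <- if (is.null(sig)) {
      tibble(position = character(0), base = character(0),
             frequency = numeric(0), z_plus1 = numeric(0))
    } else {
      left_join(tidy(sig), rename(sig$z, z_plus1 = "z"), by = "base")
    }
    emit("end_signature", library, sig_tbl, paste0(library, "_signature.tsv"))

    list(library = library, group = group, abundance = ab, linkage = lz)
  })

  groups <- split(per_lib, vapply(per_lib, `[[`, character(1), "group"))
  ref_group <- config$reference_group
  if (!ref_group %in% names(groups)) {
    abort(sprintf("Reference group '%s' not present among libraries.",
                  ref_group), class = "pirnakit_bad_config")
  }
  group_ab <- purrr::map(groups, function(g) {
    average_abundance(purrr::map(g, "abundance"),
                      library = g[[1]]$group)
  })
  group_lz <- purrr::map(groups, function(g) {
    bind_rows(purrr::map(g, "linkage")) |>
      group_by(.data$transposon) |>
      summarise(n_pairs = sum(.data$n_pairs),
                z10 = if (all(is.na(.data$z10))) NA_real_ else
                  mean(.data$z10, na.rm = TRUE),
                .groups = "drop")
  })

  for (g in setdiff(names(groups), ref_group)) {
    usable_ab <- !anyNA(group_ab[[ref_group]]$abundance) &&
      !anyNA(group_ab[[g]]$abundance)
    if (usable_ab) {
      fc <- fold_changes(group_ab[[ref_group]], group_ab[[g]],
                         eps = config$eps)
      emit("fold_changes", g, fc, paste0("fold_changes_", g, ".tsv"))
    } else {
      warn(sprintf("Skipping fold changes for group %s (NA abundances).", g))
    }
    shared <- inner_join(filter(group_lz[[ref_group]], !is.na(.data$z10)),
                         filter(group_lz[[g]], !is.na(.data$z10)),
                         by = "transposon")
    if (nrow(shared) >= 3) {
      cmp <- compare_linkage(group_lz[[ref_group]], group_lz[[g]],
                             labels = c(ref_group, g))
      emit("linkage_comparison", g,
           mutate(tidy(cmp), .before = 1,
                  t = unname(cmp$test$statistic),
                  p_value = cmp$test$p.value),
           paste0("linkage_comparison_", g, ".tsv"))
    } else {
      warn(sprintf(
        "Skipping linkage comparison for group %s (%d defined transposons).",
        g, nrow(shared)))
    }
  }

  manifest <- bind_rows(manifest)
  inputs <- c(config$libraries$fastq, config$transposon_fasta,
              config$infra_fasta, config$hp_fasta)
  meta <- list(
    parameters = config[setdiff(names(config), "libraries")],
    libraries = config$libraries,
    input_md5 = setNames(unname(tools::md5sum(inputs)), inputs),
    outputs = manifest)
  jsonlite::write_json(meta, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
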