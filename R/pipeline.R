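#' Pipeline configuration
#'
#' @param input_dir directory with `annotation.tsv` and `structures/` (the
#'   layout emitted by [generate_cohort()]).
#' @param out_dir output directory.
#' @param radii shell radii in Angstrom, positive ascending.
#' @param motif_radius named radii (A) used for motif extraction per class
#'   group: 6 A for diterpene-skeleton producers (classes I and I/II), 8 A
#'   for intermediate-producing class II enzymes.
#' @param ssn_threshold percent-identity threshold of the SSN stage.
#' @param ligand_codes HETATM residue names of the bound substrate.
#' @param fingerprint_radius,fingerprint_bits ECFP parameters.
#' @param query_dir optional directory of query PDB structures for motif
#'   search.
#' @param bh Benjamini-Hochberg flag for the correlation report.
#' @param seed RNG seed recorded and set before the run.
#' @param force recompute stages whose outputs already exist.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, radii = c(4, 6, 8, 10),
                            motif_radius = c(I = 6, I_II = 6, II = 8),
                            ssn_threshold = 50, ligand_codes = "LIG",
                            fingerprint_radius = 2, fingerprint_bits = 2048,
                            query_dir = NULL, bh = FALSE, seed = 1,
                            force = FALSE) {
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be positive and strictly ascending")
  structure(list(input_dir = input_dir, out_dir = out_dir, radii = radii,
                 motif_radius = motif_radius, ssn_threshold = ssn_threshold,
                 ligand_codes = ligand_codes,
                 fingerprint_radius = fingerprint_radius,
                 fingerprint_bits = fingerprint_bits, query_dir = query_dir,
                 bh = bh, seed = seed, force = force),
            class = "pipeline_config")
}

log_stage <- function(out_dir, stage, t0, n_in, n_out, note = "") {
  row <- data.frame(stage = stage,
                    wall_s = round(as.numeric(Sys.time()) - t0, 2),
                    n_in = n_in, n_out = n_out, note = note,
                    stringsAsFactors = FALSE)
  path <- file.path(out_dir, "log.tsv")
  write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: curate -> domains -> seqsim (N/C/NC/full) ->
#' ssn -> shells (each radius) -> structsim (global + per-radius shell TM) ->
#' motifs (per class group at its stated radius) -> motif search over an
#' optional query set -> chemsim -> stats (composition/preference,
#' correlation report, same-vs-different comparisons) -> report. Every stage
#' logs its inputs and row counts to `log.tsv`; outputs already on disk are
#' reused unless `force`.
#'
#' @param config `pipeline_config`.
#' @param stages subset of stage names to run (with their dependencies
#'   loaded from disk); default all.
#' @return Invisibly, a list with the in-memory stage products.
#' @export
run_pipeline <- function(config, stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ann_path <- file.path(config$input_dir, "annotation.tsv")
  struct_dir <- file.path(config$input_dir, "structures")
  if (!file.exists(ann_path)) stop("config error: missing ", ann_path)
  if (!dir.exists(struct_dir)) stop("config error: missing ", struct_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cfg_echo <- config
  cfg_echo$force <- NULL
  yaml::write_yaml(unclass(cfg_echo), file.path(config$out_dir, "config.yaml"))
  out <- config$out_dir
  want <- function(s) is.null(stages) || s %in% stages
  fresh <- function(...) {
    config$force || !all(file.exists(file.path(out, c(...))))
  }
  env <- new.env()

  run_stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fn(), error = function(e) {
      log_stage(out, name, t0, NA, NA, paste("FAILED:", conditionMessage(e)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  # curate
  env$records <- run_stage("curate", function() {
    t0 <- as.numeric(Sys.time())
    recs <- read_annotation(ann_path)
    jsonlite::write_json(dataset_summary(recs),
                         file.path(out, "dataset_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage(out, "curate", t0, nrow(attr(recs, "errors")) + length(recs),
              length(recs),
              paste0(nrow(attr(recs, "errors")), " malformed rows"))
    recs
  })
  recs <- env$records
  ids <- names(recs)

  # domains
  if (want("domains")) {
    run_stage("domains", function() {
      t0 <- as.numeric(Sys.time())
      if (fresh("domains.tsv")) {
        rows <- lapply(recs, function(r) {
          sp <- split_domains(r)
          data.frame(accession = r$accession, n_len = nchar(sp$N),
                     c_len = nchar(sp$C), stringsAsFactors = FALSE)
        })
        write.table(do.call(rbind, rows), file.path(out, "domains.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage(out, "domains", t0, length(recs), length(recs))
    })
  }

  # seqsim
  regions <- c("N", "C", "NC", "full")
  env$seqsim <- list()
  if (want("seqsim")) {
    run_stage("seqsim", function() {
      t0 <- as.numeric(Sys.time())
      for (rg in regions) {
        f <- paste0("seqsim_", rg, ".tsv")
        if (fresh(f)) {
          m <- similarity_matrix(recs, rg)
          write_similarity_matrix(m, file.path(out, f))
        } else {
          m <- read_similarity_matrix(file.path(out, f), paste0("seq_", rg), 100)
        }
        env$seqsim[[rg]] <- m
      }
      log_stage(out, "seqsim", t0, length(recs), length(regions))
    })
  }

  # ssn
  if (want("ssn") && !is.null(env$seqsim$full)) {
    run_stage("ssn", function() {
      t0 <- as.numeric(Sys.time())
      if (fresh("ssn.tsv", "ssn.graphml")) {
        ssn <- build_ssn(env$seqsim$full, config$ssn_threshold,
                         mode = "identity", records = recs)
        write_ssn(ssn, file.path(out, "ssn"))
        env$ssn <- ssn
      }
      log_stage(out, "ssn", t0, length(recs),
                if (is.null(env$ssn)) NA else igraph::ecount(env$ssn$graph),
                paste("threshold", config$ssn_threshold))
    })
  }

  # shells
  env$structures <- list()
  env$shells <- list()
  if (want("shells") || want("structsim") || want("motifs") || want("stats")) {
    run_stage("shells", function() {
      t0 <- as.numeric(Sys.time())
      files <- file.path(struct_dir, paste0(ids, ".pdb"))
      have <- file.exists(files)
      for (k in which(have)) {
        sm <- read_structure(files[k], ligand_codes = config$ligand_codes)
        env$structures[[ids[k]]] <- sm
      }
      for (r in config$radii) {
        dir.create(file.path(out, "shells", paste0("r", r)),
                   recursive = TRUE, showWarnings = FALSE)
        env$shells[[as.character(r)]] <- lapply(env$structures, function(sm) {
          sh <- extract_shell(sm$model, sm$ligand, r)
          p <- file.path(out, "shells", paste0("r", r),
                         paste0(sm$model$structure_id, ".pdb"))
          if ((config$force || !file.exists(p)) && nrow(sh$atoms) > 0)
            write_shell_pdb(sh, p)
          sh
        })
      }
      log_stage(out, "shells", t0, sum(have),
                sum(have) * length(config$radii))
    })
  }

  # structsim
  env$tm <- list()
  if (want("structsim")) {
    run_stage("structsim", function() {
      t0 <- as.numeric(Sys.time())
      if (fresh("tm_global.tsv")) {
        m <- tm_similarity_matrix(lapply(env$structures, `[[`, "model"),
                                  "tm_global")
        write_similarity_matrix(m, file.path(out, "tm_global.tsv"))
      } else {
        m <- read_similarity_matrix(file.path(out, "tm_global.tsv"),
                                    "tm_global", 1)
      }
      env$tm[["global"]] <- m
      for (r in config$radii) {
        f <- paste0("tm_shell_", r, ".tsv")
        if (fresh(f)) {
          m <- shell_tm_matrix(env$shells[[as.character(r)]], r)
          write_similarity_matrix(m, file.path(out, f))
        } else {
          m <- read_similarity_matrix(file.path(out, f),
                                      paste0("tm_shell_", r), 1)
        }
        env$tm[[paste0("shell_", r)]] <- m
      }
      log_stage(out, "structsim", t0, length(env$structures),
                length(env$tm))
    })
  }

  # motifs
  env$motifs <- list()
  if (want("motifs")) {
    run_stage("motifs", function() {
      t0 <- as.numeric(Sys.time())
      groups <- list(I = c("I", "I_II"), II = "II")
      classes <- vapply(recs, function(r) r$class_label, character(1))
      for (gname in names(groups)) {
        radius <- unname(config$motif_radius[[gname]])
        members <- ids[classes %in% groups[[gname]]]
        shells <- env$shells[[as.character(radius)]][
          intersect(members, names(env$shells[[as.character(radius)]]))]
        shells <- Filter(function(s) nrow(residue_table(s)) >= 4, shells)
        if (length(shells) < 2) next
        aln <- align_sites(shells)
        motif <- tryCatch(extract_motif(aln), error = function(e) NULL)
        if (is.null(motif)) next
        env$motifs[[gname]] <- motif
        write_motif(motif, file.path(out, paste0("motif_", gname, ".json")))
        write.table(conservation_table(aln),
                    file.path(out, paste0("conservation_", gname, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage(out, "motifs", t0, length(recs), length(env$motifs))
    })
  }

  # motif search over external queries
  if (want("motif_search") && !is.null(config$query_dir) &&
      length(env$motifs) > 0) {
    run_stage("motif_search", function() {
      t0 <- as.numeric(Sys.time())
      qfiles <- list.files(config$query_dir, pattern = "\\.pdb$",
                           full.names = TRUE)
      rows <- list()
      for (qf in qfiles) {
        q <- read_structure(qf)$model
        for (gname in names(env$motifs)) {
          mm <- search_motif(env$motifs[[gname]], q, policy = "relaxed")
          tab <- motif_match_table(mm)
          if (nrow(tab) > 0) tab$motif <- gname
          rows[[length(rows) + 1L]] <- tab
        }
      }
      tab <- do.call(rbind, rows)
      write.table(tab, file.path(out, "motif_matches.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log_stage(out, "motif_search", t0, length(qfiles),
                if (is.null(tab)) 0 else nrow(tab))
    })
  }

  # chemsim
  if (want("chemsim")) {
    run_stage("chemsim", function() {
      t0 <- as.numeric(Sys.time())
      f <- "product_dsc.tsv"
      if (fresh(f)) {
        m <- product_similarity_matrix(recs, config$fingerprint_radius,
                                       config$fingerprint_bits)
        write_similarity_matrix(m, file.path(out, f))
      } else {
        m <- read_similarity_matrix(file.path(out, f), "product_dsc", 1)
      }
      env$product_dsc <- m
      log_stage(out, "chemsim", t0, length(recs), 1)
    })
  }

  # stats
  if (want("stats")) {
    run_stage("stats", function() {
      t0 <- as.numeric(Sys.time())
      for (r in config$radii) {
        f <- paste0("preference_r", r, ".tsv")
        if (fresh(f)) {
          pt <- preference_table(env$shells[[as.character(r)]], recs)
          write.table(pt, file.path(out, f), sep = "\t", quote = FALSE,
                      row.names = FALSE)
        }
      }
      factors <- c(env$seqsim,
                   if (!is.null(env$tm$global)) list(tm_global = env$tm$global),
                   env$tm[grep("^shell_", names(env$tm))],
                   if (!is.null(env$product_dsc))
                     list(product_dsc = env$product_dsc))
      names(factors) <- vapply(factors, function(f) f$kind, character(1))
      if (length(factors) >= 2) {
        crep <- correlation_report(factors, bh = config$bh)
        write.table(crep, file.path(out, "correlation_report.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        env$correlations <- crep
      }
      # same-vs-different comparisons per factor and key
      rows <- list()
      for (key in c("substrate", "product_skeleton")) {
        part <- pair_partition(recs, key)
        for (fk in names(factors)) {
          pv <- partition_values(factors[[fk]], part)
          if (length(pv$same) < 3 || length(pv$different) < 3) next
          gc <- group_compare(pv$same, pv$different)
          rows[[length(rows) + 1L]] <- data.frame(
            key = key, factor = fk, U = gc$U, p = gc$p,
            median_same = gc$summary_same[["median"]],
            median_different = gc$summary_different[["median"]],
            q1_same = gc$summary_same[["q1"]],
            q3_same = gc$summary_same[["q3"]],
            q1_different = gc$summary_different[["q1"]],
            q3_different = gc$summary_different[["q3"]],
            n_same = length(pv$same), n_different = length(pv$different),
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows) > 0) {
        env$group_comparisons <- do.call(rbind, rows)
        write.table(env$group_comparisons,
                    file.path(out, "group_comparisons.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage(out, "stats", t0, length(recs),
                length(factors))
    })
  }

  if (want("report")) {
    run_stage("report", function() {
      t0 <- as.numeric(Sys.time())
      txt <- summarize_run(out)
      writeLines(txt, file.path(out, "report.txt"))
      log_stage(out, "report", t0, NA, length(txt))
    })
  }
  invisible(as.list(env))
}

#' Human-readable summary of a pipeline run
#'
#' Per-factor quartiles, same-versus-different comparisons, the Pearson
#' correlation grid, and the motif inventory; missing stages are flagged
#' "not run".
#'
#' @param out_dir a pipeline output directory.
#' @return Character vector of report lines.
#' @export
summarize_run <- function(out_dir) {
  lines <- c("diTPS sequence-structure-product analysis report",
             paste("output:", out_dir), "")
  # factor quartiles
  lines <- c(lines, "== Similarity factor quartiles ==")
  mats <- list.files(out_dir, pattern = "^(seqsim_|tm_|product_dsc).*\\.tsv$")
  if (length(mats) == 0) {
    lines <- c(lines, "  [not run]")
  } else {
    for (f in mats) {
      m <- read_similarity_matrix(file.path(out_dir, f),
                                  sub("\\.tsv$", "", f))
      v <- m$values[upper.tri(m$values)]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      q <- five_number(v)
      lines <- c(lines, sprintf(
        "  %-18s min %.3f  Q1 %.3f  median %.3f  Q3 %.3f  max %.3f",
        sub("\\.tsv$", "", f), q[1], q[2], q[3], q[4], q[5]))
    }
  }
  lines <- c(lines, "", "== Same vs different substrate/product ==")
  gpath <- file.path(out_dir, "group_comparisons.tsv")
  if (file.exists(gpath)) {
    g <- read.delim(gpath)
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf(
        "  %-16s %-14s U=%-8.0f p=%-10.3g median same %.3f vs diff %.3f",
        g$key[i], g$factor[i], g$U[i], g$p[i], g$median_same[i],
        g$median_different[i]))
    }
  } else lines <- c(lines, "  [not run]")
  lines <- c(lines, "", "== Pearson correlations between factors ==")
  cpath <- file.path(out_dir, "correlation_report.tsv")
  if (file.exists(cpath)) {
    cr <- read.delim(cpath)
    for (i in seq_len(nrow(cr))) {
      lines <- c(lines, sprintf("  %-14s : %-14s r=%6.3f p=%.3g n=%d",
                                cr$factor_a[i], cr$factor_b[i], cr$r[i],
                                cr$p[i], cr$n[i]))
    }
  } else lines <- c(lines, "  [not run]")
  lines <- c(lines, "", "== 3D motif inventory ==")
  mpaths <- list.files(out_dir, pattern = "^motif_.*\\.json$")
  if (length(mpaths) == 0) {
    lines <- c(lines, "  [not run]")
  } else {
    for (f in mpaths) {
      m <- read_motif(file.path(out_dir, f))
      lines <- c(lines, sprintf(
        "  %-12s %d positions (%s), support %d sites, ref %s",
        sub("\\.json$", "", f), nrow(m$positions),
        paste(m$positions$consensus, collapse = ""), m$support,
        m$reference_id))
    }
  }
  lines
}
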