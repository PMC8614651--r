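# One-call pipeline: load -> validate -> per-sequence metrics -> per-group
# analyses -> fixed layout of TSV reports plus a checksummed manifest.

fmt_table <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- signif(df[[nm]], 6)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(fmt_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

pct_cols <- function(df, cols) {
  for (nm in intersect(cols, names(df))) df[[nm]] <- 100 * df[[nm]]
  df
}

#' Run the full codon-usage analysis pipeline
#'
#' Loads and validates a grouped CDS dataset, computes per-sequence
#' composition, ENC (observed/expected/ratio), RSCU, protein properties
#' and PR2 coordinates, then per-group summaries, neutrality regressions,
#' RSCU classification, correspondence analyses, the correlation battery
#' and the pooled ENC-ratio histogram, writing every result as a TSV under
#' `outdir`. Composition tables are reported on the percent scale;
#' plot-scale quantities (GC3 in `cub.tsv`, neutrality inputs) stay as
#' fractions. The run is deterministic for a given config and inputs; a
#' `manifest.json` lists each output with its MD5 checksum and `run.log`
#' records accepted/rejected counts per group.
#'
#' @param fasta Path to the input FASTA of coding sequences.
#' @param groups Path to the two-column TSV mapping sequence ids to group
#'   labels.
#' @param outdir Output directory (created if absent).
#' @param correlation_method `"spearman"` (default) or `"pearson"` for the
#'   correlation battery.
#' @param pr2_mode `"all_codons"` (default) or `"fourfold_only"`.
#' @param coa_input `"rscu"` (default) or `"counts"`.
#' @param coa_scope `"per_group"` (default) or `"joint"`.
#' @param enc_ratio_bin_width Bin width of the ENC-ratio histogram.
#' @param make_plots Also write PNG figures?
#' @return Invisibly, the manifest list (paths, checksums, counts).
#' @export
run_pipeline <- function(fasta, groups, outdir,
                         correlation_method = c("spearman", "pearson"),
                         pr2_mode = c("all_codons", "fourfold_only"),
                         coa_input = c("rscu", "counts"),
                         coa_scope = c("per_group", "joint"),
                         enc_ratio_bin_width = 0.05,
                         make_plots = FALSE) {
  correlation_method <- match.arg(correlation_method)
  pr2_mode <- match.arg(pr2_mode)
  coa_input <- match.arg(coa_input)
  coa_scope <- match.arg(coa_scope)
  stopifnot(is.numeric(enc_ratio_bin_width), enc_ratio_bin_width > 0)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "correlations"), showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ds <- load_dataset(fasta, groups)
  glab <- dataset_groups(ds)
  for (g in ds$groups) {
    note("group ", g, ": ", sum(glab == g), " accepted")
  }
  note("rejected: ", nrow(ds$rejected))
  outputs <- character(0)
  emit <- function(df, name) {
    outputs <<- c(outputs, write_tsv(df, file.path(outdir, name)))
  }

  emit(ds$rejected, "rejected.tsv")

  # per-sequence tables ------------------------------------------------
  comp <- composition_table(ds)
  cub <- suppressWarnings(cub_table(ds))
  prot <- protein_table(ds)
  emit(pct_cols(comp, PCT_METRICS), "composition.tsv")
  emit(cub, "cub.tsv")
  emit(prot[, c("seq_id", "group", "gravy", "aromaticity")], "protein.tsv")

  rsc <- rscu_matrix(ds)
  emit(cbind(data.frame(seq_id = rownames(rsc), group = glab,
                        stringsAsFactors = FALSE),
             as.data.frame(rsc)), "rscu.tsv")

  # PR2 ---------------------------------------------------------------
  pr2_rows <- lapply(ds$sequences, function(s) {
    fr <- if (pr2_mode == "fourfold_only") {
      third_position_fractions(s, fourfold_only = TRUE)
    } else {
      composition_profile(s)
    }
    pt <- pr2_point(fr)
    data.frame(seq_id = s$seq_id, group = s$group,
               gc_bias = pt$gc_bias, at_bias = pt$at_bias,
               defined = pt$defined, stringsAsFactors = FALSE)
  })
  pr2 <- do.call(rbind, pr2_rows)
  if (any(!pr2$defined)) {
    warning(sum(!pr2$defined), " sequence(s) with undefined PR2 ",
            "coordinates excluded from plots")
  }
  emit(pr2, "pr2.tsv")

  # group summaries ----------------------------------------------------
  metrics <- comp
  metrics$enc_obs <- cub$enc_obs
  summ_in <- metrics[, c("group", "length_nt", "gc_pct",
                         "p1", "p2", "p3", "p12")]
  summ_in$enc <- cub$enc_obs
  summ_in$gravy <- prot$gravy
  summ_in$aromaticity <- prot$aromaticity
  emit(summarize_groups(summ_in), "group_summary.tsv")

  # amino-acid usage ----------------------------------------------------
  aa_cols <- grep("^freq_", names(prot), value = TRUE)
  aa_use <- do.call(rbind, lapply(split(prot, prot$group), function(df) {
    cbind(data.frame(group = df$group[1L], stringsAsFactors = FALSE),
          as.data.frame(t(colMeans(df[, aa_cols]))))
  }))
  emit(aa_use, "aa_usage.tsv")

  # RSCU classification per group (majority vote + group-mean RSCU) ----
  cls_rows <- list()
  for (g in ds$groups) {
    sub <- rsc[glab == g, , drop = FALSE]
    mean_rscu <- colMeans(sub)
    vote <- apply(sub, 2, function(v) {
      cls <- ifelse(v > 1.6, "over_represented",
                    ifelse(v > 1, "preferred",
                           ifelse(v == 1, "unbiased", "rare")))
      names(which.max(table(cls)))
    })
    cls_rows[[g]] <- data.frame(group = g, codon = colnames(rsc),
                                aa = GENCODE[colnames(rsc)],
                                mean_rscu = mean_rscu, class = vote,
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  emit(do.call(rbind, cls_rows), "rscu_class.tsv")

  # neutrality regression per group -------------------------------------
  neut_rows <- list()
  for (g in ds$groups) {
    sub <- comp[comp$group == g, ]
    fit <- tryCatch(neutrality_fit(sub$p3, sub$p12), error = function(e) {
      warning("neutrality fit skipped for group '", g, "': ",
              conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    neut_rows[[g]] <- data.frame(group = g, slope = fit$slope,
                                 intercept = fit$intercept, r = fit$r,
                                 p_value = fit$p_value, n = fit$n,
                                 stringsAsFactors = FALSE)
  }
  neut <- if (length(neut_rows) > 0L) do.call(rbind, neut_rows) else
    data.frame(group = character(), slope = numeric(), intercept = numeric(),
               r = numeric(), p_value = numeric(), n = integer())
  emit(neut, "neutrality.tsv")

  # ENC-ratio histogram (pooled) ----------------------------------------
  ok_ratio <- cub$enc_ratio[is.finite(cub$enc_ratio)]
  hist_df <- if (length(ok_ratio) > 0L) {
    h <- enc_ratio_histogram(ok_ratio, enc_ratio_bin_width)
    data.frame(bin_lo = utils::head(h$bin_edges, -1L),
               bin_hi = h$bin_edges[-1L], count = h$bin_counts)
  } else {
    data.frame(bin_lo = numeric(), bin_hi = numeric(), count = integer())
  }
  emit(hist_df, "enc_ratio_hist.tsv")

  # correspondence analysis ---------------------------------------------
  coa_scopes <- if (coa_scope == "joint") list(all = seq_along(glab)) else
    split(seq_along(glab), glab)
  coa_rows <- list(); coa_cols <- list(); coa_inert <- list()
  coa_results <- list()
  for (g in names(coa_scopes)) {
    ix <- coa_scopes[[g]]
    if (length(ix) < 2L) {
      warning("correspondence analysis skipped for group '", g,
              "': fewer than 2 sequences")
      next
    }
    tab <- if (coa_input == "counts") {
      m <- t(vapply(ds$sequences[ix], function(s) {
        as.numeric(count_codons(s))
      }, numeric(length(SENSE_CODONS))))
      dimnames(m) <- list(dataset_ids(ds)[ix], SENSE_CODONS)
      m
    } else {
      rsc[ix, , drop = FALSE]
    }
    res <- tryCatch(suppressWarnings(correspondence_analysis(tab)),
                    error = function(e) {
                      warning("correspondence analysis skipped for group '",
                              g, "': ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    coa_results[[g]] <- res
    coa_rows[[g]] <- data.frame(group = g, seq_id = rownames(res$row_coords),
                                f1 = res$row_coords[, 1L],
                                f2 = if (ncol(res$row_coords) >= 2L)
                                  res$row_coords[, 2L] else 0,
                                stringsAsFactors = FALSE, row.names = NULL)
    coa_cols[[g]] <- data.frame(group = g, codon = rownames(res$col_coords),
                                f1 = res$col_coords[, 1L],
                                f2 = if (ncol(res$col_coords) >= 2L)
                                  res$col_coords[, 2L] else 0,
                                stringsAsFactors = FALSE, row.names = NULL)
    coa_inert[[g]] <- data.frame(group = g,
                                 axis = seq_along(res$singular_values),
                                 singular_value = res$singular_values,
                                 inertia_fraction = res$inertias,
                                 stringsAsFactors = FALSE)
  }
  emit(do.call(rbind, coa_rows), "coa_rows.tsv")
  emit(do.call(rbind, coa_cols), "coa_cols.tsv")
  emit(do.call(rbind, coa_inert), "coa_inertia.tsv")
  if (coa_scope == "joint" && length(coa_results) == 1L) {
    cent <- project_groups(coa_results[["all"]], glab)
    emit(data.frame(group = rownames(cent), as.data.frame(cent),
                    stringsAsFactors = FALSE), "coa_centroids.tsv")
  }

  # correlation battery --------------------------------------------------
  suppressWarnings({
    batteries <- list(nuc_vs_nuc3 = nucleotide_pairs(),
                      enc_vs_positions = enc_position_pairs(),
                      gc_vs_positions = gc_position_pairs())
    for (bname in names(batteries)) {
      cm <- correlation_matrix(metrics, batteries[[bname]],
                               method = correlation_method)
      for (g in unique(cm$group)) {
        emit(cm[cm$group == g, ],
             file.path("correlations", paste0(g, "_", bname, ".tsv")))
      }
    }
    emit(rscu_gc3_correlation(rsc, comp$gc3, glab,
                              method = correlation_method),
         "rscu_gc3_heatmap.tsv")
  })

  if (make_plots) {
    outputs <- c(outputs, pipeline_plots(outdir, hist_df, pr2, comp, neut,
                                         coa_rows))
  }

  writeLines(log_lines, file.path(outdir, "run.log"))
  manifest <- list(
    config = list(fasta = fasta, groups = groups,
                  correlation_method = correlation_method,
                  pr2_mode = pr2_mode, coa_input = coa_input,
                  coa_scope = coa_scope,
                  enc_ratio_bin_width = enc_ratio_bin_width),
    counts = list(accepted = length(ds$sequences),
                  rejected = nrow(ds$rejected),
                  per_group = as.list(table(glab))),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = sub(paste0("^", outdir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
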