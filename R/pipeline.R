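# output files carry a provenance header: tool version, config hash, seed
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

.write_tsv_with_header <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# primequant %s\tconfig=%s\tseed=%s",
                     as.character(utils::packageVersion("primequant")),
                     config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' End-to-end primer design pipeline
#'
#' Chains the design workflow: trim each family's members to low-repeat
#' cores, align the cores, build a neighbor-joining tree, cut it into
#' subfamilies, and design a hierarchy of discriminating primer sets per
#' family. With an `out_dir`, writes `primers.tsv`, `unresolved.tsv`,
#' `classification.tsv`, `cores.tsv` and one Newick tree per family, each
#' file headed by the tool version, a hash of the configuration and the
#' seed.
#'
#' @param panel An `allele_panel` (may contain several families).
#' @param k_subfamilies Named integer vector or single integer: number of
#'   subfamilies per family label (families with fewer than 3 members are
#'   left uncut).
#' @param constraints A `primer_constraints`.
#' @param rules A `binding_rules`.
#' @param trim_threshold Repeat-coverage threshold for core extraction.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Seed recorded in output headers (the design path itself is
#'   deterministic).
#' @return List of class `design_run`: per family `classification`,
#'   `design`, `tree`, plus combined `primers` and `unresolved` data
#'   frames and the core `report`.
#' @export
run_design <- function(panel, k_subfamilies = 2L,
                       constraints = primer_constraints(),
                       rules = binding_rules(),
                       trim_threshold = 0.1,
                       out_dir = NULL, seed = 0L) {
  stopifnot(inherits(panel, "allele_panel"))
  families <- names(panel$family_index)
  if (!is.null(names(k_subfamilies))) {
    unknown <- setdiff(names(k_subfamilies), families)
    if (length(unknown)) {
      stop("unknown family label(s) in k_subfamilies: ",
           paste(unknown, collapse = ", "))
    }
  }
  trimmed <- trim_cores(panel, threshold = trim_threshold)
  per_family <- list()
  primers <- list(); unresolved <- list(); assignments <- list()
  for (fam in families) {
    ids <- panel$family_index[[fam]]
    if (length(ids) < 2) {
      unresolved[[length(unresolved) + 1L]] <- data.frame(
        name = fam, level = "family",
        reason = "family has a single member; nothing to align",
        stringsAsFactors = FALSE
      )
      next
    }
    aln <- align_group(trimmed$panel$sequences[ids], source = "core")
    tree <- build_tree(aln)
    k <- if (!is.null(names(k_subfamilies))) {
      if (fam %in% names(k_subfamilies)) k_subfamilies[[fam]] else 2L
    } else {
      k_subfamilies[1]
    }
    k <- min(as.integer(k), length(ids))
    classification <- cut_subfamilies(tree, mode = "k_groups", value = k)
    design <- design_hierarchy(classification, aln, panel, constraints, rules)
    per_family[[fam]] <- list(classification = classification,
                              design = design, tree = tree)
    if (nrow(design$sets)) {
      d <- design$sets; d$family <- fam
      primers[[length(primers) + 1L]] <- d
    }
    if (nrow(design$unresolved)) {
      u <- design$unresolved; u$family <- fam
      unresolved[[length(unresolved) + 1L]] <- u
    }
    a <- classification$assignment; a$family <- fam
    assignments[[length(assignments) + 1L]] <- a
  }
  res <- structure(
    list(
      families = per_family,
      primers = if (length(primers)) do.call(rbind, primers) else
        data.frame(name = character(0)),
      unresolved = if (length(unresolved))
        do.call(rbind, lapply(unresolved, function(u) {
          if (!"family" %in% names(u)) u$family <- u$name
          u
        })) else data.frame(name = character(0)),
      classification = if (length(assignments)) do.call(rbind, assignments) else
        data.frame(id = character(0)),
      core_report = trimmed$report
    ),
    class = "design_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- .config_hash(list(k = k_subfamilies, constraints = constraints,
                           rules = rules, trim = trim_threshold))
    .write_tsv_with_header(res$primers, file.path(out_dir, "primers.tsv"), h, seed)
    .write_tsv_with_header(res$unresolved, file.path(out_dir, "unresolved.tsv"), h, seed)
    .write_tsv_with_header(res$classification,
                           file.path(out_dir, "classification.tsv"), h, seed)
    .write_tsv_with_header(res$core_report, file.path(out_dir, "cores.tsv"), h, seed)
    for (fam in names(per_family)) {
      ape::write.tree(per_family[[fam]]$tree,
                      file.path(out_dir, paste0("tree_", fam, ".nwk")))
    }
  }
  res
}

#' @export
print.design_run <- function(x, ...) {
  cat("design_run:", nrow(x$primers), "primer set(s),",
      nrow(x$unresolved), "unresolved node(s) across",
      length(x$families), "family(ies)\n")
  invisible(x)
}

#' Validate a primer table against a panel
#'
#' Runs [validate_specificity()] for every primer set and returns (and
#' optionally writes) the verdict table.
#'
#' @param panel An `allele_panel`.
#' @param primer_table Data frame with `name`, `forward`, `reverse`,
#'   `target_ids` (comma-separated).
#' @param rules A `binding_rules`.
#' @param out_path Optional TSV output path.
#' @param seed Seed recorded in the output header.
#' @return Data frame: `name`, `verdict`, `target_ids`, `amplified_ids`.
#' @export
run_validate <- function(panel, primer_table, rules = binding_rules(),
                         out_path = NULL, seed = 0L) {
  rows <- lapply(seq_len(nrow(primer_table)), function(i) {
    rep_ <- validate_specificity(as.list(primer_table[i, ]), panel, rules)
    data.frame(
      name = rep_$name, verdict = rep_$verdict,
      target_ids = paste(rep_$target_ids, collapse = ","),
      amplified_ids = paste(rep_$amplified_ids, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_path)) {
    .write_tsv_with_header(out, out_path, .config_hash(list(rules = rules)), seed)
  }
  out
}

#' Quantify transcripts from Ct tables
#'
#' The absolute quantification path: per primer set and sample, replicate
#' Ct values are cleaned with [remove_outliers()], averaged, converted to
#' template mass through the standard curve, to attomoles through the
#' coding-region length, and normalized to a reference primer set measured
#' in the same samples. Ct means outside the curve's reliable window are
#' flagged, not dropped.
#'
#' @param ct_table Data frame with columns `primer_set`, `sample` and
#'   replicate Ct columns (named `ct*`); `NA` replicates are ignored.
#' @param curve A `standard_curve`.
#' @param lengths Named numeric vector: coding-region length (bp) per
#'   primer set (the length of the transcript each assay reports on).
#' @param reference Name of the reference primer set (must be present in
#'   every sample).
#' @param mass_model `"ds"` or `"ss"` per-base molar mass.
#' @param max_dev Outlier cutoff in Ct cycles.
#' @param out_path Optional TSV output path.
#' @param seed Seed recorded in the output header.
#' @return Data frame: `primer_set`, `sample`, `n_replicates_used`,
#'   `mean_ct`, `ct_flagged`, `conc_ng_ul`, `amount_amol`,
#'   `normalized` (amol per amol of reference).
#' @export
run_quantify <- function(ct_table, curve, lengths, reference,
                         mass_model = c("ds", "ss"), max_dev = 0.5,
                         out_path = NULL, seed = 0L) {
  stopifnot(inherits(curve, "standard_curve"))
  mass_model <- match.arg(mass_model)
  ct_cols <- grep("^ct", names(ct_table), value = TRUE)
  if (!length(ct_cols)) stop("ct_table needs replicate columns named 'ct*'")
  missing_len <- setdiff(unique(ct_table$primer_set), names(lengths))
  if (length(missing_len)) {
    stop("no coding length for primer set(s): ",
         paste(missing_len, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(ct_table)), function(i) {
    cts <- as.numeric(ct_table[i, ct_cols])
    cts <- cts[!is.na(cts)]
    mask <- if (length(cts) >= 2) remove_outliers(cts, max_dev) else
      rep(TRUE, length(cts))
    mct <- mean(cts[mask])
    conc <- ct_to_concentration(curve, mct)
    amol <- ng_to_amol(as.numeric(conc), lengths[[ct_table$primer_set[i]]],
                       mass_model)
    data.frame(
      primer_set = ct_table$primer_set[i], sample = ct_table$sample[i],
      n_replicates_used = sum(mask), mean_ct = mct,
      ct_flagged = as.logical(attr(conc, "flagged")),
      conc_ng_ul = as.numeric(conc), amount_amol = amol,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ref <- out[out$primer_set == reference, c("sample", "amount_amol")]
  if (!all(unique(out$sample) %in% ref$sample)) {
    stop("reference primer set '", reference, "' missing for sample(s): ",
         paste(setdiff(unique(out$sample), ref$sample), collapse = ", "))
  }
  out$normalized <- normalize_amount(
    out$amount_amol, ref$amount_amol[match(out$sample, ref$sample)]
  )
  if (!is.null(out_path)) {
    h <- .config_hash(list(curve = unclass(curve)[c("slope", "intercept")],
                           reference = reference, mass_model = mass_model,
                           max_dev = max_dev))
    .write_tsv_with_header(out, out_path, h, seed)
  }
  out
}

#' Log-scale expression profile plot
#'
#' Plots normalized transcript amounts (amol per amol of reference)
#' against sample on a logarithmic axis, one line per primer set --
#' the wide dynamic range of storage-protein transcripts makes a linear
#' axis unreadable.
#'
#' @param quant Output of [run_quantify()] (uses `primer_set`, `sample`,
#'   `normalized`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the sample-by-set matrix plotted.
#' @export
plot_expression <- function(quant, ...) {
  m <- tapply(quant$normalized, list(quant$sample, quant$primer_set), mean)
  graphics::matplot(seq_len(nrow(m)), m, type = "b", log = "y",
                    xaxt = "n", xlab = "sample", pch = 19,
                    ylab = "amol target per amol reference", ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m))
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = seq_len(ncol(m)), cex = 0.7, bty = "n")
  invisible(m)
}
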