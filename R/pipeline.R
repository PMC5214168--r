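# End-to-end orchestration: data (real or synthetic) -> diversity tables ->
# FST -> outlier scan -> pi_T-S -> HKA / mlHKA -> MK-PRF -> TSV reports.
# All randomness flows from one master seed through named per-stage
# substreams, so stages are independently reproducible.

write_report <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multilocus selection scan
#'
#' Orchestrates every stage over a set of locus alignments: per-species
#' diversity summaries, FST with permutation tests, the reference-calibrated
#' (pi_sil, D_sil) outlier scan, the pi_T-S differentiation test, the
#' multilocus HKA test on candidate loci, per-candidate mlHKA
#' likelihood-ratio tests, and hierarchical MK-PRF estimation of selection
#' coefficients for all loci. Either pass alignments plus a
#' \code{locus_classes} table, or a \code{generator_config} to run on
#' synthetic data.
#'
#' @param alignments Named list of \code{locus_alignment} objects, or
#'   \code{NULL} to generate synthetic data from \code{config}.
#' @param locus_classes Data frame with columns \code{locus}, \code{class}
#'   (\code{"candidate"}/\code{"reference"}); taken from the generator truth
#'   when \code{config} is used.
#' @param config Optional \code{\link{generator_config}}.
#' @param out_dir Optional directory for TSV reports and the run manifest.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param scan_reps Replicates for the outlier-scan null.
#' @param pi_ts_reps Replicates per locus for the pi_T-S test.
#' @param hka_reps Parametric-bootstrap replicates for the HKA test.
#' @param fst_perms Permutations for the FST test (0 skips).
#' @param mkprf_cycles,mkprf_burn_in,mkprf_thin MK-PRF chain settings.
#' @param alpha Flagging level for the outlier scan.
#' @param T_div Fixed divergence time for mlHKA and MK-PRF.
#' @return List of class \code{selscan_run} with all stage outputs.
#' @export
run_selection_scan <- function(alignments = NULL, locus_classes = NULL,
                               config = NULL, out_dir = NULL, seed = 1L,
                               scan_reps = 1e4, pi_ts_reps = 2000L,
                               hka_reps = 1000L, fst_perms = 1000L,
                               mkprf_cycles = 5e4, mkprf_burn_in = 1e3,
                               mkprf_thin = 10L, alpha = 0.05, T_div = 15) {
  truth <- NULL
  if (is.null(alignments)) {
    if (is.null(config)) stop("provide alignments or a generator config")
    gen <- run_stage("generate",
      generate_dataset(config, seed = derive_seed(seed, "generate"),
                       dir = if (!is.null(out_dir))
                         file.path(out_dir, "data") else NULL))
    alignments <- gen$alignments
    truth <- gen$truth
    locus_classes <- truth[, c("locus", "class")]
  }
  if (is.null(locus_classes))
    stop("locus_classes required when alignments are supplied")
  locus_classes <- as.data.frame(locus_classes)
  cand <- locus_classes$locus[locus_classes$class == "candidate"]
  refs <- locus_classes$locus[locus_classes$class == "reference"]
  if (length(intersect(cand, refs)))
    stop("candidate and reference sets must be disjoint")
  if (length(refs) == 0L) stop("no reference loci configured")
  unknown <- setdiff(c(cand, refs), names(alignments))
  if (length(unknown))
    stop("configured locus not present in data: ",
         paste(unknown, collapse = ", "))

  cls_of <- function(id) locus_classes$class[locus_classes$locus == id]
  classes <- run_stage("classify", lapply(alignments, classify_sites))
  species <- unique(unlist(lapply(alignments, function(a)
    unique(a$meta$species))))

  # diversity summaries
  div <- run_stage("stats", {
    d <- do.call(rbind, lapply(names(alignments), function(id) {
      s <- diversity_summary(alignments[[id]], classes[[id]])
      s$class <- cls_of(id)
      s
    }))
    write_report(d, out_dir, "diversity.tsv")
    d
  })

  # FST among populations, per locus x species
  fst <- run_stage("fst", {
    rows <- list()
    for (id in names(alignments)) {
      for (sp in unique(alignments[[id]]$meta$species)) {
        sub <- subset_species(alignments[[id]], sp)
        tab <- table(sub$meta$population)
        if (length(tab) < 2L || any(tab < 2L)) next
        f <- hudson_fst(sub, "population", classes[[id]],
                        n_perm = fst_perms,
                        seed = derive_seed(seed, paste0("fst_", id, sp)))
        rows[[length(rows) + 1L]] <- data.frame(
          locus = id, species = sp, class = cls_of(id), fst = f$fst,
          permutation_p = f$permutation_p, stringsAsFactors = FALSE)
      }
    }
    f <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(f)) write_report(f, out_dir, "fst.tsv")
    f
  })

  # reference-calibrated outlier scan per species
  outliers <- run_stage("scan", {
    res <- list()
    for (sp in species) {
      dsp <- div[div$species == sp, ]
      refsum <- dsp[dsp$class == "reference", ]
      candsum <- dsp[dsp$class == "candidate", ]
      if (!nrow(candsum)) next
      null <- calibrate_null(
        data.frame(theta = refsum$theta_w_sil, L = refsum$sites_sil),
        n_chrom = round(stats::median(candsum$n)), reps = scan_reps,
        seed = derive_seed(seed, paste0("scan_", sp)))
      fl <- flag_outliers(
        data.frame(locus = candsum$locus_id, pi_sil = candsum$pi_sil,
                   D_sil = candsum$tajima_d_sil), null, alpha = alpha)
      fl$species <- sp
      res[[sp]] <- fl
    }
    o <- do.call(rbind, res)
    write_report(o, out_dir, "outliers.tsv")
    o
  })

  # pi_T-S per candidate locus
  pi_ts <- run_stage("pi_ts", {
    rows <- lapply(cand, function(id) {
      a <- alignments[[id]]
      if (length(unique(a$meta$species)) < 2L) return(NULL)
      r <- pi_ts_test(a, classes[[id]], reps = pi_ts_reps,
                      seed = derive_seed(seed, paste0("pits_", id)))
      data.frame(locus = id, pi_T = r$pi_T, pi_S = r$pi_S, pi_TS = r$pi_TS,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 significant = r$significant,
                 skipped = !is.null(r$skipped), stringsAsFactors = FALSE)
    })
    p <- do.call(rbind, rows)
    if (!is.null(p)) write_report(p, out_dir, "pi_ts.tsv")
    p
  })

  # HKA + mlHKA per species on candidate loci
  hka <- list()
  mlhka <- list()
  hka_rows <- list()
  mlhka_rows <- list()
  run_stage("hka", {
    for (sp in species) {
      tab <- do.call(rbind, lapply(cand, function(id) {
        sub <- subset_species(alignments[[id]], sp)
        sd <- silent_poly_div(sub, classes[[id]])
        data.frame(locus = id, S = sd$S, D = sd$D, L = sd$L, n = sd$n)
      }))
      h <- hka_test(tab, sim_reps = hka_reps,
                    seed = derive_seed(seed, paste0("hka_", sp)))
      hka[[sp]] <- h
      hka_rows[[sp]] <- data.frame(
        species = sp, X2 = h$X2, df = h$df, p_chi = h$p_chi,
        p_sim = h$p_sim %||% NA_real_)

      fit0 <- mlhka_fit(tab, character(0), T_div = T_div)
      rows <- lapply(cand, function(id) {
        t1 <- mlhka_locus_test(tab, id, T_div = T_div)
        data.frame(species = sp, locus = id,
                   lnL_neutral = t1$neutral$logLik,
                   lnL_selection = t1$selection$logLik,
                   LR = t1$lrt$LR, p = t1$lrt$p, k_hat = t1$k_hat,
                   valid = t1$lrt$valid, stringsAsFactors = FALSE)
      })
      mlhka[[sp]] <- fit0
      mlhka_rows[[sp]] <- do.call(rbind, rows)
    }
  })
  write_report(do.call(rbind, hka_rows), out_dir, "hka.tsv")
  write_report(do.call(rbind, mlhka_rows), out_dir, "mlhka.tsv")

  # MK-PRF per species over all loci
  mkprf <- run_stage("mkprf", {
    res <- list()
    for (sp in species) {
      tabs <- do.call(rbind, lapply(names(alignments), function(id) {
        sub <- subset_species(alignments[[id]], sp)
        pol <- polarize_variants(sub, classes[[id]])
        build_mk_table(pol, n = nrow(sub$mat), locus_id = id,
                       class = cls_of(id))
      }))
      res[[sp]] <- run_mkprf(tabs, cycles = mkprf_cycles,
                             burn_in = mkprf_burn_in, thin = mkprf_thin,
                             seed = derive_seed(seed, paste0("mkprf_", sp)),
                             tau = T_div)
    }
    prf_tab <- do.call(rbind, lapply(names(res), function(sp) {
      s <- res[[sp]]$summary
      s$species <- sp
      s
    }))
    write_report(prf_tab, out_dir, "mkprf.tsv")
    res
  })

  if (!is.null(out_dir)) {
    manifest <- c(
      paste0("package_version=", as.character(utils::packageVersion(
        "popselscan"))),
      paste0("r_version=", R.version.string),
      paste0("seed=", seed),
      paste0("n_loci=", length(alignments)),
      paste0("candidates=", paste(cand, collapse = ",")),
      paste0("references=", paste(refs, collapse = ",")),
      paste0("scan_reps=", scan_reps),
      paste0("pi_ts_reps=", pi_ts_reps),
      paste0("hka_reps=", hka_reps),
      paste0("fst_perms=", fst_perms),
      paste0("mkprf_cycles=", mkprf_cycles),
      paste0("alpha=", alpha),
      paste0("T_div=", T_div))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }

  structure(list(
    diversity = div, fst = fst, outliers = outliers, pi_ts = pi_ts,
    hka = hka, hka_table = do.call(rbind, hka_rows),
    mlhka = mlhka, mlhka_table = do.call(rbind, mlhka_rows),
    mkprf = mkprf, truth = truth, seed = seed),
    class = "selscan_run")
}

#' @export
print.selscan_run <- function(x, ...) {
  cat("selection-scan run (seed ", x$seed, ")\n", sep = "")
  cat("  loci: ", nrow(x$diversity) / max(1,
      length(unique(x$diversity$species))), " (",
      sum(x$diversity$class == "candidate") /
        max(1, length(unique(x$diversity$species))), " candidate)\n",
      sep = "")
  if (!is.null(x$hka_table)) {
    cat("  HKA:\n")
    print(x$hka_table, digits = 4)
  }
  if (!is.null(x$outliers))
    cat("  outlier flags:", sum(x$outliers$flagged, na.rm = TRUE), "of",
        nrow(x$outliers), "\n")
  if (!is.null(x$pi_ts))
    cat("  pi_T-S significant:", sum(x$pi_ts$significant, na.rm = TRUE),
        "of", nrow(x$pi_ts), "\n")
  invisible(x)
}
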