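.log <- function(fmt, ...) {
    lvl <- getOption("imprintKit.logLevel", "info")
    if (identical(lvl, "quiet")) return(invisible())
    message(sprintf(paste0("[imprintKit] ", fmt), ...))
}

.runConfigDefaults <- function() {
    list(
        min_delta = 0.2, max_gap = 300, min_cpgs = 10, fdr = 0.05,
        genotype_min_depth = 10, genotype_min_minor_frac = 0.25,
        ase_min_depth = 10, ase_mono_frac = 0.95,
        peak_min_fold = 5, peak_min_width = 200,
        precip_min_allele_frac = 0.25, precip_min_depth = 20,
        island_min_len = 200, island_min_gc = 0.5, island_min_obs_exp = 0.6,
        strand_merge = FALSE, seed = 1, out_dir = ".", log_level = "info")
}

.runConfigRanges <- list(
    min_delta = c(0, 1), max_gap = c(1, Inf), min_cpgs = c(1, Inf),
    fdr = c(0, 1), genotype_min_depth = c(0, Inf),
    genotype_min_minor_frac = c(0, 0.5), ase_min_depth = c(0, Inf),
    ase_mono_frac = c(0.5, 1), peak_min_fold = c(1, Inf),
    peak_min_width = c(1, Inf), precip_min_allele_frac = c(0, 0.5),
    precip_min_depth = c(0, Inf), island_min_len = c(1, Inf),
    island_min_gc = c(0, 1), island_min_obs_exp = c(0, Inf))

#' Read a run configuration
#'
#' Loads a YAML (or JSON) file of stage thresholds, merged over the package
#' defaults. Unknown keys are rejected and every numeric threshold is
#' checked against its documented range, so a typo cannot silently change an
#' analysis.
#'
#' @param path YAML/JSON config path, or \code{NULL} for pure defaults.
#' @return a named list of thresholds and run settings.
#' @export
readRunConfig <- function(path = NULL) {
    cfg <- .runConfigDefaults()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        unknown <- setdiff(names(user), names(cfg))
        if (length(unknown))
            stop("unknown config key(s): ", paste(unknown, collapse = ", "))
        cfg[names(user)] <- user
    }
    for (k in names(.runConfigRanges)) {
        rg <- .runConfigRanges[[k]]
        v <- cfg[[k]]
        if (!is.numeric(v) || v < rg[1] || v > rg[2])
            stop(sprintf("config '%s' = %s outside [%g, %g]",
                         k, format(v), rg[1], rg[2]))
    }
    cfg
}
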