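# Feature registry: the 127-entry multi-domain feature bank. Entries are
# (name, domain, arity, extractor); per-channel extractors have signature
# f(x, fs, ctx) and spatial extractors f(window, roles). The shipped JSON
# manifest (inst/extdata/feature_manifest.json) mirrors this table so the
# bank's composition is inspectable and swappable without code changes.

registry_env <- new.env(parent = emptyenv())

spec_row <- function(name, domain, arity, fn, kind = "channel") {
  tibble::tibble(name = name, domain = domain, arity = as.integer(arity),
                 kind = kind, fn = list(fn))
}

#' Logarithmic variant of a registered feature
#'
#' Wraps a base extractor in the signed log transform
#' `sign(v) * log(1 + |v| / eps_scale)`, preserving sign and monotonicity
#' while compressing the voluminous values abnormal EMG can produce.
#'
#' @param spec One-row registry entry (as in [feature_registry()]`$specs`).
#' @param name Name for the variant (default `"L" + base name`).
#' @param eps_scale Scale constant of the transform (default 1).
#' @return A one-row registry tibble for the variant.
#' @export
log_variant <- function(spec, name = NULL, eps_scale = 1) {
  base_fn <- spec$fn[[1]]
  name <- name %||% paste0("L", spec$name)
  f <- function(x, fs, ctx) log_scale(base_fn(x, fs, ctx), eps_scale)
  spec_row(name, spec$domain, spec$arity, f, spec$kind)
}

build_registry_specs <- function() {
  td <- list(
    spec_row("MAV",    "TD", 1, feat_mav),
    spec_row("IEMG",   "TD", 1, feat_iemg),
    spec_row("RMS",    "TD", 1, feat_rms),
    spec_row("VAR",    "TD", 1, feat_var),
    spec_row("SSI",    "TD", 1, feat_ssi),
    spec_row("WL",     "TD", 1, feat_wl),
    spec_row("ZC",     "TD", 1, feat_zc),
    spec_row("SSC",    "TD", 1, feat_ssc),
    spec_row("WAMP",   "TD", 1, feat_wamp),
    spec_row("MMAV1",  "TD", 1, feat_mmav1),
    spec_row("MMAV2",  "TD", 1, feat_mmav2),
    spec_row("MMAV5",  "TD", 1, feat_mmav5),
    spec_row("EWL",    "TD", 1, feat_ewl),
    spec_row("NSV",    "TD", 1, feat_nsv),
    spec_row("MSR",    "TD", 1, feat_msr),
    spec_row("RSM0",   "TD", 1, feat_rsm0),
    spec_row("RSD1",   "TD", 1, feat_rsd1),
    spec_row("RSD2",   "TD", 1, feat_rsd2),
    spec_row("ROG",    "TD", 1, feat_rog),
    spec_row("CARD",   "TD", 1, feat_card),
    spec_row("CRD",    "TD", 1, feat_crd),
    spec_row("AR2",    "TD", 2, feat_ar(2)),
    spec_row("AR3",    "TD", 3, feat_ar(3)),
    spec_row("AR4",    "TD", 4, feat_ar(4)),
    spec_row("AR5",    "TD", 5, feat_ar(5)),
    spec_row("AR6",    "TD", 6, feat_ar(6)),
    spec_row("CC",     "TD", 4, feat_cc),
    spec_row("HJA",    "TD", 1, feat_hja),
    spec_row("HJM",    "TD", 1, feat_hjm),
    spec_row("HJC",    "TD", 1, feat_hjc),
    spec_row("MHW",    "TD", 1, feat_mhw),
    spec_row("MTW",    "TD", 1, feat_mtw),
    spec_row("LOG",    "TD", 1, feat_log),
    spec_row("DAMV",   "TD", 1, feat_damv),
    spec_row("DASDV",  "TD", 1, feat_dasdv),
    spec_row("AAC",    "TD", 1, feat_aac),
    spec_row("MYOP",   "TD", 1, feat_myop),
    spec_row("TM3",    "TD", 1, feat_tm3),
    spec_row("TM4",    "TD", 1, feat_tm4),
    spec_row("TM5",    "TD", 1, feat_tm5),
    spec_row("VORD",   "TD", 1, feat_vord),
    spec_row("MAVSLP", "TD", 1, feat_mavslp),
    spec_row("HIST",   "TD", 3, feat_hist),
    spec_row("MFL",    "TD", 1, feat_mfl),
    spec_row("SKEW",   "TD", 1, feat_skew),
    spec_row("KURT",   "TD", 1, feat_kurt),
    spec_row("PKAMP",  "TD", 1, feat_pkamp),
    spec_row("RNG",    "TD", 1, feat_rng),
    spec_row("STDV",   "TD", 1, feat_stdv),
    spec_row("MEANV",  "TD", 1, feat_meanv),
    spec_row("MEDAV",  "TD", 1, feat_medav),
    spec_row("COVV",   "TD", 1, feat_covv),
    spec_row("IQRV",   "TD", 1, feat_iqrv),
    spec_row("MADV",   "TD", 1, feat_madv))
  td_tbl <- dplyr::bind_rows(td)
  log_bases <- c("MAV", "SSI", "CARD", "IEMG", "RMS", "VAR", "WL", "DAMV",
                 "DASDV", "TM3", "TM4", "TM5", "MSR", "ROG", "RSM0", "RSD1",
                 "RSD2", "AAC", "EWL", "MMAV1", "MMAV2", "MMAV5", "MFL",
                 "HJA", "STDV", "PKAMP")
  td_log <- dplyr::bind_rows(lapply(log_bases, function(b)
    log_variant(td_tbl[td_tbl$name == b, ])))
  fd <- dplyr::bind_rows(
    spec_row("MNF",   "FD", 1, feat_mnf),
    spec_row("MDF",   "FD", 1, feat_mdf),
    spec_row("MNP",   "FD", 1, feat_mnp),
    spec_row("TTP",   "FD", 1, feat_ttp),
    spec_row("PKF",   "FD", 1, feat_pkf),
    spec_row("PSP",   "FD", 1, feat_psp),
    spec_row("PSR",   "FD", 1, feat_psr),
    spec_row("SM1",   "FD", 1, feat_sm1),
    spec_row("SM2",   "FD", 1, feat_sm2),
    spec_row("SMN",   "FD", 1, feat_smn),
    spec_row("VCF",   "FD", 1, feat_vcf),
    spec_row("MASP",  "FD", 1, feat_masp),
    spec_row("FDD",   "FD", 1, feat_fdd),
    spec_row("ASM",   "FD", 1, feat_asm),
    spec_row("ER",    "FD", 1, feat_er),
    spec_row("PERC2", "FD", 1, feat_perc2),
    spec_row("MNPD",  "FD", 1, feat_mnpd),
    spec_row("SEN",   "FD", 1, feat_sen))
  fd <- dplyr::bind_rows(fd, log_variant(fd[fd$name == "MASP", ], name = "MLASP"))
  tfd <- dplyr::bind_rows(
    spec_row("DWT",   "TFD", 1, feat_dwt),
    spec_row("SWT",   "TFD", 1, feat_swt),
    spec_row("STFT",  "TFD", 1, feat_stft),
    spec_row("HHT",   "TFD", 1, feat_hht),
    spec_row("EWT4",  "TFD", 1, feat_ewt(4)),
    spec_row("EWT6",  "TFD", 1, feat_ewt(6)),
    spec_row("EWT8",  "TFD", 1, feat_ewt(8)),
    spec_row("EWT10", "TFD", 1, feat_ewt(10)),
    spec_row("EWP4",  "TFD", 1, feat_ewp(4)),
    spec_row("EWP6",  "TFD", 1, feat_ewp(6)),
    spec_row("EWP8",  "TFD", 1, feat_ewp(8)),
    spec_row("EWP10", "TFD", 1, feat_ewp(10)),
    spec_row("WENT",  "TFD", 1, feat_went))
  frd <- dplyr::bind_rows(
    spec_row("FR1",  "FRD", 1, feat_fr(1)),
    spec_row("FR2",  "FRD", 1, feat_fr(2)),
    spec_row("FR3",  "FRD", 1, feat_fr(3)),
    spec_row("FR4",  "FRD", 1, feat_fr(4)),
    spec_row("DFA",  "FRD", 1, feat_dfa),
    spec_row("HFD",  "FRD", 1, feat_hfd),
    spec_row("AEN",  "FRD", 1, feat_aen),
    spec_row("SAEN", "FRD", 1, feat_saen),
    spec_row("KFD",  "FRD", 1, feat_kfd),
    spec_row("PFD",  "FRD", 1, feat_pfd))
  sd_ <- dplyr::bind_rows(lapply(
    c("SDPR", "SDMAVR", "SDRMSR", "SDWLR", "SDSSIR"),
    function(nm) spec_row(nm, "SD", 1, feat_spatial(nm), kind = "spatial")))
  specs <- dplyr::bind_rows(td_tbl, td_log, fd, tfd, frd, sd_)
  if (anyDuplicated(specs$name))
    abort_config("duplicate feature name in registry")
  specs
}

#' The multi-domain EMG feature registry
#'
#' The default bank holds 127 features across five domains: time (TD,
#' 80 entries including the logarithmic variants), frequency (FD),
#' time-frequency (TFD), fractal (FRD) and spatial cross-channel ratios
#' (SD). Per-channel features are extracted from every channel and
#' concatenated; spatial features are computed once per segment.
#'
#' @param names Optional character vector restricting (and ordering) the
#'   registry to a subset of feature names.
#' @return A `feature_registry` with a `specs` tibble
#'   (name, domain, arity, kind, extractor).
#' @examples
#' reg <- feature_registry()
#' nrow(reg$specs)                 # 127
#' table(reg$specs$domain)
#' @export
feature_registry <- function(names = NULL) {
  if (is.null(registry_env$specs))
    registry_env$specs <- build_registry_specs()
  specs <- registry_env$specs
  if (!is.null(names)) {
    idx <- match(normalize_feature_name(names), normalize_feature_name(specs$name))
    if (anyNA(idx))
      abort_config(sprintf("unknown feature name(s): %s",
                           paste(names[is.na(idx)], collapse = ", ")))
    specs <- specs[idx, ]
  }
  structure(list(specs = specs), class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry> %d features: %s\n", nrow(x$specs),
              paste(sprintf("%s=%d", names(table(x$specs$domain)),
                            table(x$specs$domain)), collapse = ", ")))
  invisible(x)
}

#' Resolve feature names against a registry
#'
#' Names are matched case-insensitively with dashes/underscores ignored, so
#' `"EWT-4"`, `"ewt_4"` and `"EWT4"` all resolve to the same entry.
#'
#' @param names Character vector of feature names.
#' @param registry A [feature_registry()].
#' @return The canonical registry names, in registry order.
#' @export
resolve_features <- function(names, registry = feature_registry()) {
  if (length(names) == 0L) abort_config("empty feature selection")
  idx <- match(normalize_feature_name(names), normalize_feature_name(registry$specs$name))
  if (anyNA(idx))
    abort_config(sprintf("unknown feature name(s): %s",
                         paste(names[is.na(idx)], collapse = ", ")))
  registry$specs$name[sort(unique(idx))]
}

#' Read the shipped feature manifest
#'
#' @param path Manifest JSON path (defaults to the file shipped with the
#'   package).
#' @return Tibble with columns name, domain, arity.
#' @export
feature_manifest <- function(path = system.file("extdata", "feature_manifest.json",
                                                package = "snailfs")) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Feature domain lookup
#'
#' @param names Feature names.
#' @param registry A [feature_registry()].
#' @return Character vector of domains (TD/FD/TFD/FRD/SD).
#' @export
feature_domains <- function(names, registry = feature_registry()) {
  idx <- match(normalize_feature_name(names), normalize_feature_name(registry$specs$name))
  if (anyNA(idx))
    abort_config(sprintf("unknown feature name(s): %s",
                         paste(names[is.na(idx)], collapse = ", ")))
  registry$specs$domain[idx]
}
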