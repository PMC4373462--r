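#' ATC classification settings for the persistence analysis
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) system is hierarchical, so
#' drug exposure groups are defined by code *prefixes* (the conventional
#' `"A10%"` wildcard notation). `atc_config()` bundles every prefix set the
#' pipeline needs: the mono-LABA index drugs, the long-acting respiratory
#' medications that define treatment-naivety and switching, the typical
#' asthma medications used to exclude likely (late-onset) asthma patients,
#' the comorbidity medication proxies, short-acting bronchodilators (SABA)
#' and oral corticosteroids (OCS).
#'
#' Defaults: mono-LABAs are salmeterol (R03AC12), formoterol (R03AC13) and
#' indacaterol (R03AC18); asthma exclusion covers antihistamines (R06),
#' anti-allergics (R03BC), leukotriene receptor antagonists (R03DC) and
#' omalizumab (R03DX05). The inhaled-corticosteroid (R03BA), long-acting
#' muscarinic antagonist (R03BB) and fixed LABA/ICS combination (R03AK)
#' prefixes complete the long-acting set; they are exposed here because ATC
#' groups for those classes are a configuration choice, not a fixed rule.
#'
#' @param ... named overrides for any element of the default configuration.
#' @return A list of class `atc_config`.
#' @examples
#' cfg <- atc_config()
#' atc_matches("A10BA02", cfg$comorbidity_map$diabetes)
#' @export
atc_config <- function(...) {
  cfg <- list(
    laba_mono = c("R03AC12", "R03AC13", "R03AC18"),
    laba_ics_combo = "R03AK",
    ics_mono = "R03BA",
    lama = "R03BB",
    asthma_exclusion = c("R06", "R03BC", "R03DC", "R03DX05"),
    saba = c("R03AC02", "R03AC03", "R03AB"),
    ocs = "H02AB",
    comorbidity_map = list(
      osteoporosis = "M05B",
      diabetes = "A10",
      ischaemic_heart_disease = "C01DA",
      heart_failure = c("C01AA05", "C03C"),
      dyslipidaemia = "C10",
      other_cardiovascular = c("C02", "C03", "C07", "C08", "C09"),
      depression = "N06A",
      dementia = "N06B",
      anxiety = c("N05B", "N05C"),
      psychosis = "N05A",
      rheumatic_arthritis = c("M01", "M02"),
      thyroid = "H03"
    )
  )
  cfg <- modifyList(cfg, list(...))
  cfg$long_acting <- unique(c(cfg$laba_mono, cfg$laba_ics_combo,
                              cfg$ics_mono, cfg$lama))
  flat <- c(cfg$laba_mono, cfg$long_acting, cfg$asthma_exclusion, cfg$saba,
            cfg$ocs, unlist(cfg$comorbidity_map, use.names = FALSE))
  bad <- flat[!is_valid_atc(flat)]
  if (length(bad) > 0) {
    abort(paste0("invalid ATC prefix(es): ", paste(unique(bad), collapse = ", ")),
          class = "copdpersist_atc_error")
  }
  if (!all(cfg$laba_mono %in% cfg$long_acting)) {
    abort("laba_mono prefixes must be contained in the long-acting set",
          class = "copdpersist_config_error")
  }
  structure(cfg, class = c("atc_config", "list"))
}

# ATC grammar: letter, 2 digits, letter, letter, 2 digits; valid truncations
# have 1, 3, 4, 5 or 7 characters (prefixes at any hierarchy level).
is_valid_atc <- function(code) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", toupper(code)) &
    nchar(code) %in% c(1L, 3L, 4L, 5L, 7L)
}

#' Match ATC codes against a set of prefixes
#'
#' Prefix semantics mirror the `"A10%"` wildcard convention: a code matches
#' if any prefix in the set is a leading substring of it. Matching is
#' case-insensitive and vectorised over `codes`. Adding prefixes to the set
#' can only turn non-matches into matches (monotonicity).
#'
#' @param codes character vector of full ATC codes (1-7 characters).
#' @param prefixes character vector of ATC prefixes.
#' @return Logical vector, one element per code.
#' @examples
#' atc_matches(c("A10BA02", "C10AA01"), "A10")
#' @export
atc_matches <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  codes <- toupper(codes)
  if (any(is.na(codes) | codes == "" | !is_valid_atc(codes))) {
    abort("malformed ATC code(s) supplied to atc_matches()",
          class = "copdpersist_atc_error")
  }
  if (length(prefixes) == 0) return(rep(FALSE, length(codes)))
  prefixes <- toupper(prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) {
    out <- out | startsWith(codes, p)
  }
  out
}

#' Map a mono-LABA ATC code to the medication name
#'
#' @param atc character vector of 7-character ATC codes.
#' @return Character vector: "salmeterol", "formoterol", "indacaterol" or NA.
#' @export
laba_medication <- function(atc) {
  c(R03AC12 = "salmeterol", R03AC13 = "formoterol",
    R03AC18 = "indacaterol")[toupper(atc)] |> unname()
}

#' Write / read an ATC configuration as YAML
#'
#' @param config an `atc_config` object.
#' @param path file path.
#' @return `read_atc_config` returns an `atc_config`; `write_atc_config`
#'   returns `path` invisibly.
#' @export
write_atc_config <- function(config, path) {
  stopifnot(inherits(config, "atc_config"))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "long_acting")], path)
  invisible(path)
}

#' @rdname write_atc_config
#' @export
read_atc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(atc_config, vals)
}
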