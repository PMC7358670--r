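#' Severity classes of the CLN3 disease spectrum
#'
#' The CLN3 disease spectrum is stratified into ordered severity classes,
#' from unaffected controls through heterozygous carriers and the
#' retina-only phenotype up to classical (childhood-onset
#' neurodegenerative) disease. The ordering is used throughout the
#' package: synthetic cohort generation, plotting, and the fixed-effect
#' contrast coding of the severity model all rely on it.
#'
#' @return Character vector of class labels in increasing clinical
#'   severity: `control`, `carrier`, `retina_only`, `protracted`,
#'   `delayed_classical`, `classical`.
#' @export
#' @examples
#' severity_levels()
#' severity_rank("classical")
severity_levels <- function() {
  c("control", "carrier", "retina_only", "protracted",
    "delayed_classical", "classical")
}

#' @rdname severity_levels
#' @param class_label Character vector of severity-class labels.
#' @return `severity_rank` returns the integer ordinal rank (0 = control,
#'   5 = classical) of each label.
#' @export
severity_rank <- function(class_label) {
  lv <- severity_levels()
  idx <- match(class_label, lv)
  if (anyNA(idx)) {
    stop("unknown severity class: ",
         paste(unique(class_label[is.na(idx)]), collapse = ", "),
         "; must be one of ", paste(lv, collapse = ", "))
  }
  idx - 1L
}

#' Coerce severity labels to an ordered-by-severity factor
#'
#' Returns a factor whose levels are the severity classes in increasing
#' clinical order with `control` first, so that treatment contrasts in
#' downstream models compare each class to controls.
#'
#' @param class_label Character vector of severity-class labels.
#' @param drop Drop unused levels (default `FALSE`).
#' @return A factor with levels `severity_levels()` (treatment coding,
#'   control as reference).
#' @export
severity_factor <- function(class_label, drop = FALSE) {
  severity_rank(class_label)  # validates
  f <- factor(class_label, levels = severity_levels())
  if (drop) droplevels(f) else f
}

#' Map a CLN3 genotype to its severity class
#'
#' CLN3 alleles are categorized as `truncating` (e.g. the common 1 kb
#' deletion, nonsense and frameshift variants), `mild_missense`
#' (relatively mild missense variants such as c.1000C>T), or
#' `particularly_mild_missense` (e.g. c.1213C>T). The phenotype class
#' follows from the allele combination:
#'
#' * two truncating alleles -> `classical`
#' * one truncating + one mild missense -> `delayed_classical`
#' * two particularly mild missense alleles -> `retina_only`
#' * any other combination with at least one mild missense allele
#'   (including mild + mild, mild + particularly mild, truncating +
#'   particularly mild) -> `protracted`
#'
#' The mapping is symmetric in its two arguments.
#'
#' @param allele1,allele2 Allele category strings, one of `truncating`,
#'   `mild_missense`, `particularly_mild_missense`. Vectorized.
#' @return Character vector of severity-class labels.
#' @export
#' @examples
#' classify_genotype("truncating", "truncating")          # classical
#' classify_genotype("truncating", "mild_missense")       # delayed_classical
#' classify_genotype("particularly_mild_missense",
#'                   "particularly_mild_missense")        # retina_only
classify_genotype <- function(allele1, allele2) {
  cats <- c("truncating", "mild_missense", "particularly_mild_missense")
  if (!all(allele1 %in% cats) || !all(allele2 %in% cats)) {
    bad <- setdiff(unique(c(allele1, allele2)), cats)
    stop("unknown allele category: ", paste(bad, collapse = ", "))
  }
  n <- max(length(allele1), length(allele2))
  allele1 <- rep_len(allele1, n)
  allele2 <- rep_len(allele2, n)
  mapply(function(a, b) {
    pair <- sort(c(a, b))
    if (identical(pair, c("truncating", "truncating"))) {
      "classical"
    } else if (identical(pair, c("mild_missense", "truncating"))) {
      "delayed_classical"
    } else if (identical(pair, rep("particularly_mild_missense", 2L))) {
      "retina_only"
    } else {
      # every remaining combination involves at least one (particularly)
      # mild missense allele without meeting a more specific rule
      "protracted"
    }
  }, allele1, allele2, USE.NAMES = FALSE)
}
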