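#' Qualifying-variant class rules
#'
#' Builds the roster of thirteen functional variant classes used to group
#' qualifying variants: one synonymous control class and twelve
#' non-synonymous classes spanning protein-truncating variants, in-silico
#' deleteriousness (PolyPhen-2 + SIFT), missense constraint (MPC, MTR,
#' constrained coding regions) and paralog conservation (para-Z). Classes
#' overlap by design: e.g. every "MPC 2" variant is also an "MPC 1"
#' variant, and "CCR 80" additionally requires MPC >= 1 and MTR <= the
#' ClinVar median.
#'
#' @param mpc1_min,mpc2_min MPC thresholds for the constrained ("MPC 1")
#'   and highly constrained ("MPC 2") missense classes.
#' @param mtr_clinvar_max,mtr_denovo_max MTR thresholds: the median MTR of
#'   ClinVar non-de-novo (0.825) and de-novo (0.565) pathogenic missense
#'   variants.
#' @param ccr_min Constrained-coding-region percentile for "CCR 80".
#' @param para_hc_min para-Z threshold for "paralog highly conserved";
#'   "paralog-conserved" is para-Z > 0 and "paralog-non-conserved" is
#'   para-Z <= 0.
#' @param damaging_rule `"both"` (default) requires PolyPhen-2 damaging AND
#'   SIFT deleterious for the damaging-missense class (and benign AND
#'   tolerated for the benign class); `"either"` accepts either predictor,
#'   treating a missing value as non-informative.
#' @return An object of class `class_rules` (a named list of thresholds).
#' @examples
#' rules <- class_rules()
#' qv_class_names(rules)
#' @export
class_rules <- function(mpc1_min = 1, mpc2_min = 2,
                        mtr_clinvar_max = 0.825, mtr_denovo_max = 0.565,
                        ccr_min = 80, para_hc_min = 1,
                        damaging_rule = c("both", "either")) {
  damaging_rule <- match.arg(damaging_rule)
  stopifnot(mpc2_min >= mpc1_min, mtr_denovo_max <= mtr_clinvar_max,
            ccr_min >= 0, ccr_min <= 100)
  structure(
    list(mpc1_min = mpc1_min, mpc2_min = mpc2_min,
         mtr_clinvar_max = mtr_clinvar_max, mtr_denovo_max = mtr_denovo_max,
         ccr_min = ccr_min, para_hc_min = para_hc_min,
         damaging_rule = damaging_rule),
    class = "class_rules")
}

#' @rdname class_rules
#' @param rules A `class_rules` object.
#' @export
qv_class_names <- function(rules = class_rules()) {
  c("Synonymous", "Benign missense", "Damaging missense", "PTV",
    "All functional", "MPC 1", "MPC 2", "MTR ClinVar", "MTR De Novo",
    "CCR 80", "paralog-non-conserved", "paralog-conserved",
    "paralog highly conserved")
}

#' @rdname class_rules
#' @export
nonsynonymous_classes <- function(rules = class_rules()) {
  setdiff(qv_class_names(rules), "Synonymous")
}

ptv_consequences <- function() {
  c("stop_gained", "start_lost", "frameshift", "splice_donor",
    "splice_acceptor")
}

known_consequences <- function() {
  c("synonymous", "missense", "inframe_indel", ptv_consequences(), "other")
}

# logical membership matrix: one column per class, one row per variant
class_membership <- function(variants, rules = class_rules()) {
  csq <- variants$consequence
  mis <- !is.na(csq) & csq == "missense"
  ptv <- !is.na(csq) & csq %in% ptv_consequences()
  inframe <- !is.na(csq) & csq == "inframe_indel"

  pph2 <- variants$pph2
  sift <- variants$sift
  pph2_dmg <- !is.na(pph2) & pph2 %in% c("possibly_damaging",
                                         "probably_damaging")
  pph2_ben <- !is.na(pph2) & pph2 == "benign"
  sift_del <- !is.na(sift) & sift == "deleterious"
  sift_tol <- !is.na(sift) & sift == "tolerated"
  if (rules$damaging_rule == "both") {
    damaging <- mis & pph2_dmg & sift_del
    benign <- mis & pph2_ben & sift_tol
  } else {
    damaging <- mis & (pph2_dmg | sift_del)
    benign <- mis & (pph2_ben | sift_tol) & !pph2_dmg & !sift_del
  }

  mpc1 <- mis & ge_na(variants$mpc, rules$mpc1_min)
  mtr_cv <- mis & le_na(variants$mtr, rules$mtr_clinvar_max)

  m <- cbind(
    "Synonymous" = !is.na(csq) & csq == "synonymous",
    "Benign missense" = benign,
    "Damaging missense" = damaging,
    "PTV" = ptv,
    "All functional" = ptv | inframe | damaging,
    "MPC 1" = mpc1,
    "MPC 2" = mis & ge_na(variants$mpc, rules$mpc2_min),
    "MTR ClinVar" = mtr_cv,
    "MTR De Novo" = mis & le_na(variants$mtr, rules$mtr_denovo_max),
    "CCR 80" = mis & ge_na(variants$ccr, rules$ccr_min) & mpc1 & mtr_cv,
    "paralog-non-conserved" = mis & le_na(variants$para_z, 0),
    "paralog-conserved" = mis & gt_na(variants$para_z, 0),
    "paralog highly conserved" = mis & ge_na(variants$para_z,
                                             rules$para_hc_min)
  )
  m[, qv_class_names(rules), drop = FALSE]
}
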