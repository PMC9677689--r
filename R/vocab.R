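#' Controlled vocabularies
#'
#' Default label sets used throughout the package. The gene set is the four
#' mismatch-repair genes whose pathogenic variants cause Lynch syndrome; the
#' organ vocabulary covers the Lynch-spectrum sites plus a catch-all
#' \code{"other"}. Both are configurable enumerations: [lynch_cohort()]
#' accepts alternative level sets (e.g. to add EPCAM) and validation is
#' performed against the levels stored in the cohort.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' @rdname vocabularies
#' @export
organ_vocabulary <- c("colorectum", "endometrium", "ovary", "urinary_tract",
                      "prostate", "brain", "pancreas", "biliary_tract",
                      "upper_GI", "other")

#' @rdname vocabularies
#' @export
carrier_statuses <- c("pathogenic", "non_carrier", "unknown")

genders <- c("female", "male")

AGE_MAX <- 110L
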