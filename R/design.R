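#' Factorial condition design table
#'
#' Expands a factorial screen layout — donors x engineering states x
#' organoid partners x antibody treatment x replicates — into one row per
#' culture, with a unique condition id and, for each co-culture, the id
#' of its matched immune-cell monoculture control (same donor,
#' engineering state, antibody status and replicate, organoid `"none"`).
#'
#' A 7-donor x 2-engineering-state x 3-replicate monoculture design, for
#' example, comprises 42 cultures.
#'
#' @param donors character vector of donor ids.
#' @param engineering_states character vector, e.g.
#'   `c("unmod", "stIL15")`.
#' @param organoids organoid partners; `"none"` denotes monoculture
#'   (default).
#' @param antibody logical vector of antibody-treatment levels
#'   (default `FALSE`).
#' @param replicates number of replicates per combination.
#' @return data.frame with columns `condition`, `donor`, `engineering`,
#'   `organoid`, `antibody`, `replicate`, `control` (NA for
#'   monocultures).
#' @export
condition_design <- function(donors, engineering_states,
                             organoids = "none", antibody = FALSE,
                             replicates = 1) {
  d <- expand.grid(replicate = seq_len(replicates),
                   antibody = antibody,
                   organoid = organoids,
                   engineering = engineering_states,
                   donor = donors,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("donor", "engineering", "organoid", "antibody", "replicate")]
  # antibody treatment of a monoculture is not a distinct culture
  d <- d[!(d$organoid == "none" & d$antibody), , drop = FALSE]
  id <- function(donor, eng, org, ab, rep) {
    paste0(donor, "_", eng,
           ifelse(org == "none", "", paste0("_", org)),
           ifelse(ab, "_mAb", ""), "_r", rep)
  }
  d$condition <- id(d$donor, d$engineering, d$organoid, d$antibody,
                    d$replicate)
  d$control <- ifelse(
    d$organoid == "none", NA_character_,
    id(d$donor, d$engineering, "none", FALSE, d$replicate))
  rownames(d) <- NULL
  d[, c("condition", "donor", "engineering", "organoid", "antibody",
        "replicate", "control")]
}
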