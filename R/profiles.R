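#' Build per-function-type binary drug profiles
#'
#' Turns a drug-receptor association table into one binary incidence matrix
#' per function type (carrier, target, enzyme, transporter, ...): entry
#' (i, r) is 1 exactly when drug i is associated with receptor r of that
#' type. The column space of each view is the set of distinct receptors of
#' that type observed in the table; duplicate associations are idempotent;
#' drugs with no association of a type get an all-zero row. Types present in
#' \code{types} but with no associations are skipped with a warning.
#'
#' @param associations data.frame with columns \code{drug_id},
#'   \code{receptor_id}, \code{function_type}.
#' @param drugs character vector: the drug universe in canonical order.
#'   Associations naming unknown drugs are an error.
#' @param types declared set of function types; defaults to those present.
#' @return a [ReceptorProfileSet-class].
#' @export
buildProfiles <- function(associations, drugs, types = NULL) {
  associations <- as.data.frame(associations)
  need <- c("drug_id", "receptor_id", "function_type")
  if (!all(need %in% names(associations)))
    stop("associations need columns: ", paste(need, collapse = ", "))
  drugs <- as.character(drugs)
  unknown <- setdiff(unique(associations$drug_id), drugs)
  if (length(unknown))
    stop("associations name unknown drugs: ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  if (is.null(types)) types <- sort(unique(associations$function_type))
  stray <- setdiff(unique(associations$function_type), types)
  if (length(stray))
    stop("associations carry undeclared function types: ",
         paste(stray, collapse = ", "))

  profiles <- list()
  for (ty in types) {
    sub <- associations[associations$function_type == ty, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no associations of type '", ty, "'; view skipped")
      next
    }
    receptors <- sort(unique(as.character(sub$receptor_id)))
    m <- matrix(0L, length(drugs), length(receptors),
                dimnames = list(drugs, receptors))
    m[cbind(match(sub$drug_id, drugs),
            match(sub$receptor_id, receptors))] <- 1L
    profiles[[ty]] <- m
  }
  new("ReceptorProfileSet", drugIds = drugs, profiles = profiles)
}

#' Pairwise Euclidean profile distance
#'
#' Distance between two drugs within one function-type view: the Euclidean
#' distance between their binary receptor profiles,
#' \eqn{\sqrt{\sum_r (x_{ir} - x_{jr})^2}} (for binary rows this is the
#' square root of the Hamming distance). Symmetric with zero diagonal.
#'
#' @param profile binary N x R matrix (one view of a
#'   [ReceptorProfileSet-class]), or the set itself plus a \code{type}.
#' @param type when \code{profile} is a [ReceptorProfileSet-class], the view
#'   to use.
#' @return N x N distance matrix.
#' @export
euclidDistance <- function(profile, type = NULL) {
  if (is(profile, "ReceptorProfileSet")) {
    stopifnot(!is.null(type))
    profile <- profileMatrix(profile, type)
  }
  as.matrix(stats::dist(profile, method = "euclidean"))
}
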