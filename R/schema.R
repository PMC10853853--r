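#' PHI taxonomy used throughout the package
#'
#' The package ships a fixed taxonomy of protected health information (PHI)
#' with 20 fine-grained categories nested inside 6 coarse-grained categories
#' (Date, Age, Name, Location, Profession, ID), the schema commonly used for
#' de-identification of Taiwanese discharge summaries.
#'
#' @return An object of class `phi_schema`: a list with elements
#'   `coarse_types` (character(6)), `fine_types` (character(20)) and
#'   `fine_to_coarse` (named character, fine type -> coarse type).
#' @examples
#' sch <- phi_schema()
#' sch$fine_to_coarse[["Doctor"]]      # "Name"
#' length(sch$fine_types)              # 20
#' @export
phi_schema <- function() {
  fine_to_coarse <- c(
    "Date"             = "Date",
    "Age"              = "Age",
    "Patient"          = "Name",
    "Person"           = "Name",
    "Doctor"           = "Name",
    "Named location"   = "Location",
    "Nationality"      = "Location",
    "Region"           = "Location",
    "Country"          = "Location",
    "City"             = "Location",
    "Hospital"         = "Location",
    "Department"       = "Location",
    "Room"             = "Location",
    "Number"           = "Location",
    "School"           = "Location",
    "Generic location" = "Location",
    "Market"           = "Location",
    "Profession"       = "Profession",
    "ID number"        = "ID",
    "Medical record"   = "ID"
  )
  structure(
    list(
      coarse_types   = c("Date", "Age", "Name", "Location", "Profession", "ID"),
      fine_types     = names(fine_to_coarse),
      fine_to_coarse = fine_to_coarse
    ),
    class = "phi_schema"
  )
}

#' @export
print.phi_schema <- function(x, ...) {
  cat("<phi_schema> ", length(x$fine_types), " fine types in ",
      length(x$coarse_types), " coarse types\n", sep = "")
  for (ct in x$coarse_types) {
    fines <- names(x$fine_to_coarse)[x$fine_to_coarse == ct]
    cat("  ", ct, ": ", paste(fines, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Map fine-grained PHI types to their coarse-grained category
#'
#' @param fine_types Character vector of fine type labels.
#' @param schema A `phi_schema`, defaults to the packaged taxonomy.
#' @return Character vector of coarse type labels.
#' @export
coarse_of <- function(fine_types, schema = phi_schema()) {
  out <- unname(schema$fine_to_coarse[fine_types])
  if (anyNA(out)) {
    bad <- unique(fine_types[is.na(out)])
    stop("unknown fine PHI type(s): ", paste(bad, collapse = ", "))
  }
  out
}

validate_fine_types <- function(fine_types, schema = phi_schema()) {
  bad <- setdiff(unique(fine_types), schema$fine_types)
  if (length(bad)) {
    stop("fine type(s) not in schema: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
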