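# De-identification against a fixed protected-field profile, plus the
# Study Comments sharing annotation.

# The default removal profile: twenty header attributes that carry
# potentially identifying information (accession/institution/physician
# identifiers, birth dates, age, address, insurance and language codes,
# alternate patient names and IDs).
.PROTECTED_TAGS <- c(
  "0008,0050", "0008,0080", "0008,0090", "0008,0096", "0008,1048",
  "0008,1049", "0008,1050", "0008,1052", "0008,1060", "0008,1062",
  "0010,0030", "0010,0050", "0010,0101", "0010,1000", "0010,1001",
  "0010,1002", "0010,1005", "0010,1010", "0010,1040", "0010,1060")

.ANNOTATION_TAG <- "0032,4000"  # Study Comments

#' The protected-field anonymization profile
#'
#' By default the profile lists the 20 protected tags removed before data
#' leaves the user's machine, with action `"remove"` (delete the
#' attribute). An alternative `"blank"` action replaces values with the
#' empty string instead. The Study Comments annotation tag is never part
#' of the protected set.
#'
#' @param protected Character vector of `"gggg,eeee"` tags.
#' @param action `"remove"` or `"blank"`.
#' @return An `anonymization_profile` object.
#' @export
anonymization_profile <- function(protected = .PROTECTED_TAGS,
                                  action = c("remove", "blank")) {
  action <- match.arg(action)
  protected <- tolower(protected)
  if (.ANNOTATION_TAG %in% protected)
    stop("the annotation tag (0032,4000) cannot be protected")
  structure(list(protected = protected, action = action,
                 annotation_tag = .ANNOTATION_TAG),
            class = "anonymization_profile")
}

#' Load an anonymization profile from a YAML or JSON config file
#'
#' The file holds a list/array `protected` of `"gggg,eeee"` tag strings and
#' an optional `action`; this allows alternative de-identification schemes
#' to be expressed without code changes.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return An [anonymization_profile()].
#' @export
load_profile <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  anonymization_profile(protected = unlist(cfg$protected),
                        action = if (is.null(cfg$action)) "remove"
                                 else cfg$action)
}

#' Apply an anonymization profile to one entity
#'
#' Deletes (or blanks) every protected attribute. All other attributes and
#' the pixel data are untouched, and the operation is idempotent: applying
#' the profile to already-clean data is the identity.
#'
#' @param entity A [dicom_entity()].
#' @param profile An [anonymization_profile()].
#' @return The de-identified entity.
#' @export
apply_profile <- function(entity, profile = anonymization_profile()) {
  for (tag in profile$protected) {
    if (!is.null(entity$tags[[tag]])) {
      if (profile$action == "remove") entity <- dcm_remove(entity, tag)
      else entity$tags[[tag]] <- ""
    }
  }
  entity
}

#' Construct a sharing annotation
#'
#' The user name and the project, subject and session identifiers that
#' route data into the archive. All four fields must be non-empty and use
#' only the allowed identifier characters (see [identifier_valid()]).
#'
#' @param user,project,subject,session Identifier strings.
#' @param validate Check the identifier rule (disable to build candidate
#'   annotations for [validate_labels()]).
#' @return A `share_annotation` object.
#' @export
share_annotation <- function(user, project, subject, session,
                             validate = TRUE) {
  note <- structure(list(user = user, project = project,
                         subject = subject, session = session),
                    class = "share_annotation")
  if (validate) {
    bad <- names(which(!vapply(note, identifier_valid, TRUE)))
    if (length(bad))
      stop("validation error: invalid identifier for ",
           paste(bad, collapse = ", "),
           " (allowed: A-Z a-z 0-9 _ -, length 1-64)")
  }
  note
}

#' Check an identifier against the allowed character rule
#'
#' Identifiers may use letters, digits, underscore and hyphen, length 1-64.
#'
#' @param x Character scalar.
#' @return `TRUE` or `FALSE`.
#' @export
identifier_valid <- function(x) {
  length(x) == 1 && !is.na(x) && grepl("^[A-Za-z0-9_-]{1,64}$", x)
}

#' Serialize / parse a sharing annotation
#'
#' The wire format stored in Study Comments is
#' `incf:user=<u>;project=<p>;subject=<s>;session=<e>` with fields in fixed
#' order; the identifier character rule makes escaping unnecessary, so
#' serialization is a bijection on valid annotations.
#'
#' @param note A [share_annotation()].
#' @return `serialize_annotation`: the wire string. `parse_annotation`: a
#'   `share_annotation`, or `NULL` if the string does not conform.
#' @export
serialize_annotation <- function(note) {
  sprintf("incf:user=%s;project=%s;subject=%s;session=%s",
          note$user, note$project, note$subject, note$session)
}

#' @rdname serialize_annotation
#' @param text Study Comments content.
#' @export
parse_annotation <- function(text) {
  if (length(text) != 1 || is.na(text)) return(NULL)
  pat <- paste0("^incf:user=([A-Za-z0-9_-]+);project=([A-Za-z0-9_-]+);",
                "subject=([A-Za-z0-9_-]+);session=([A-Za-z0-9_-]+)$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (length(m) != 5) return(NULL)
  share_annotation(m[2], m[3], m[4], m[5])
}

#' Write the sharing annotation into an entity
#'
#' Stores the serialized annotation in Study Comments (0032,4000),
#' replacing any prior content of that field. Identifiers are validated
#' before anything is written.
#'
#' @param entity A [dicom_entity()].
#' @param note A [share_annotation()].
#' @return The annotated entity.
#' @export
annotate <- function(entity, note) {
  bad <- names(which(!vapply(
    note[c("user", "project", "subject", "session")], identifier_valid,
    TRUE)))
  if (length(bad))
    stop("validation error: invalid identifier for ",
         paste(bad, collapse = ", "))
  dcm_set(entity, .ANNOTATION_TAG, serialize_annotation(note), vr = "LT")
}

#' Verify that entities conform to an anonymization profile
#'
#' Reports every occurrence of a protected attribute, with any value
#' including the empty string, as a violation. This is the server-side
#' conformance check run on arrival: any violation causes the whole
#' session to be rejected.
#'
#' @param entities List of [dicom_entity()].
#' @param profile An [anonymization_profile()].
#' @return An `anonymization_audit`: data frame `violations` with columns
#'   `filepath`, `tag`, `name`, and a logical `clean` (true iff no
#'   violations).
#' @export
verify_anonymization <- function(entities, profile = anonymization_profile()) {
  rows <- lapply(entities, function(e) {
    hit <- intersect(names(e$tags), profile$protected)
    if (length(hit) == 0) return(NULL)
    data.frame(filepath = as.character(e$filepath), tag = hit,
               name = dcm_tag_name(hit), stringsAsFactors = FALSE)
  })
  violations <- do.call(rbind, rows)
  if (is.null(violations))
    violations <- data.frame(filepath = character(0), tag = character(0),
                             name = character(0), stringsAsFactors = FALSE)
  structure(list(violations = violations, clean = nrow(violations) == 0),
            class = "anonymization_audit")
}

#' @export
print.anonymization_audit <- function(x, ...) {
  if (x$clean) cat("<anonymization_audit> clean\n")
  else {
    cat("<anonymization_audit>", nrow(x$violations), "violation(s):\n")
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}
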