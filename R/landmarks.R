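#' Canonical craniometric landmark schema
#'
#' The 56-point schema used by the template and all synthetic specimens:
#' 12 midline points and 22 bilateral pairs (`_l` / `_r` suffixes). The
#' classical names (porion, orbitale, nasion, basion, inion, lambda, ...)
#' follow Martin's nomenclature; region suffixes mark schematic points near,
#' rather than exactly at, the classical position.
#'
#' @return character vector of 56 landmark names.
#' @export
landmark_schema <- function() {
  midline <- c("nasion", "glabella", "bregma", "vertex_point", "obelion",
               "lambda", "opisthocranion", "inion", "opisthion_region",
               "basion_region", "subspinale_region", "rhinion")
  bilateral <- c("porion", "orbitale", "zygion", "frontomalare", "euryon",
                 "asterion", "mastoidale", "frontotemporale", "dacryon",
                 "ectoconchion", "zygomaxillare", "alare", "jugale",
                 "stephanion", "pterion", "auriculare", "krotaphion",
                 "zygoorbitale", "supraorbital_point", "infraorbital_point",
                 "sphenion", "coronale")
  c(midline, paste0(rep(bilateral, each = 2), c("_l", "_r")))
}

#' Named anatomical landmark set
#'
#' An ordered set of named 3D points (mm) tied to the canonical 56-name
#' schema. Landmarks may be missing (absent rows); duplicates are rejected.
#'
#' @param points numeric matrix with 3 columns, one row per landmark.
#' @param names character vector of landmark names (rownames of `points`
#'   are used when `names` is NULL).
#' @param schema schema id string recorded on the object.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, names = NULL, schema = "cranioform-56") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("landmark points must have 3 columns")
  if (is.null(names)) names <- rownames(points)
  if (is.null(names) || length(names) != nrow(points))
    stop("each landmark needs a name")
  if (anyDuplicated(names)) stop("duplicate landmark names")
  dimnames(points) <- list(names, NULL)
  structure(list(points = points, schema = schema), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks (schema %s)\n",
              nrow(x$points), x$schema))
  invisible(x)
}

#' Accessors for landmark sets
#' @param lms a [landmark_set()].
#' @return `landmark_names`: character vector; `landmark_points`: the
#'   named coordinate matrix; `missing_landmarks`: schema names absent from
#'   the set.
#' @export
landmark_names <- function(lms) rownames(lms$points)

#' @rdname landmark_names
#' @export
landmark_points <- function(lms) lms$points

#' @rdname landmark_names
#' @export
missing_landmarks <- function(lms) setdiff(landmark_schema(), landmark_names(lms))

#' Read / write landmark CSV files
#'
#' The landmark dialect is a CSV with header `name,x,y,z`, coordinates in
#' mm, one row per landmark; a missing landmark is simply an absent row.
#'
#' @param path file path.
#' @param lms a [landmark_set()].
#' @return `read_landmarks` returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z")
  landmark_set(as.matrix(df[, c("x", "y", "z")]), names = df$name)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lms, path) {
  df <- data.frame(name = landmark_names(lms), landmark_points(lms))
  colnames(df) <- c("name", "x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subset shared names, in the order of `names`
.landmark_subset <- function(lms, names) {
  landmark_set(lms$points[names, , drop = FALSE], names, lms$schema)
}
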