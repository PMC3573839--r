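#' Contours of one delineated structure
#'
#' A structure is delineated by closed polygons drawn on individual image
#' slices. A slice may carry several polygons: disjoint segments, or nested
#' outlines forming holes ("void interior") under the even-odd rule. Polygons
#' are implicitly closed — the last vertex connects back to the first; a
#' duplicated closing vertex is tolerated and dropped.
#'
#' @param name text label of the structure.
#' @param slices named list mapping 0-based slice index (as character) to a
#'   list of polygons; each polygon a numeric n x 2 matrix of in-plane
#'   vertices in mm, n >= 3.
#' @param role `"analysed"` (default) or `"reference"`; a reference contour
#'   selects RMS deviation analysis over standard-deviation analysis.
#' @return An object of class `structure_contours`.
#' @export
structure_contours <- function(name, slices, role = c("analysed", "reference")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_parse("structure name must be a non-empty string")
  if (length(slices) == 0L) {
    slices <- stats::setNames(list(), character())
  }
  keys <- names(slices)
  if (is.null(keys) || any(!nzchar(keys)))
    stop_parse(sprintf("structure '%s': slices must be keyed by slice index", name))
  idx <- suppressWarnings(as.integer(keys))
  if (any(is.na(idx)) || any(idx < 0L))
    stop_parse(sprintf("structure '%s': slice keys must be non-negative integers", name))
  slices <- lapply(seq_along(slices), function(s) {
    polys <- slices[[s]]
    if (!is.list(polys))
      stop_parse(sprintf("structure '%s', slice %s: expected a list of polygons",
                         name, keys[s]))
    lapply(seq_along(polys), function(p) {
      check_polygon(polys[[p]], name, keys[s], p)
    })
  })
  names(slices) <- keys
  slices <- slices[order(idx)]
  structure(list(name = name, role = role, slices = slices),
            class = "structure_contours")
}

check_polygon <- function(v, name, slice, p) {
  v <- as.matrix(v)
  if (ncol(v) != 2L || !is.numeric(v) || anyNA(v))
    stop_parse(sprintf(
      "structure '%s', slice %s: polygon %d must be a numeric n x 2 vertex matrix",
      name, slice, p))
  # drop an explicit closing vertex equal to the first
  n <- nrow(v)
  if (n >= 2L && all(abs(v[n, ] - v[1, ]) <= 1e-12)) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L)
    stop_parse(sprintf(
      "structure '%s', slice %s: polygon %d has %d vertices (need >= 3)",
      name, slice, p, nrow(v)))
  if (abs(polygon_area(v)) <= 1e-12)
    stop_parse(sprintf(
      "structure '%s', slice %s: polygon %d has zero area", name, slice, p))
  dimnames(v) <- NULL
  v
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

contoured_slices_of <- function(structure) {
  keep <- vapply(structure$slices, function(p) length(p) > 0L, logical(1))
  sort(as.integer(names(structure$slices)[keep]))
}

#' @export
print.structure_contours <- function(x, ...) {
  ns <- length(x$slices)
  np <- sum(vapply(x$slices, length, integer(1)))
  cat(sprintf("<structure_contours '%s' (%s): %d slice%s, %d polygon%s>\n",
              x$name, x$role, ns, if (ns == 1) "" else "s",
              np, if (np == 1) "" else "s"))
  invisible(x)
}

#' Read a contour file
#'
#' Reads the package's JSON contour interchange format: a `grid` block
#' (origin, spacing, shape; mm, 0-based slice keys) and a `structures` array,
#' each structure holding closed polygons per slice. Unknown top-level keys
#' are ignored with a warning.
#'
#' @param path path to a JSON contour file.
#' @return A list of class `contour_set` with elements `structures` (list of
#'   [structure_contours()]) and `grid` ([image_grid()]).
#' @seealso [write_contours()]
#' @export
read_contours <- function(path) {
  if (!file.exists(path))
    stop_parse(sprintf("contour file '%s' does not exist", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_parse(sprintf("malformed JSON in '%s': %s",
                                       path, conditionMessage(e))))
  known <- c("grid", "structures")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning(sprintf("ignoring unknown top-level key(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  if (is.null(doc$grid))
    stop_parse(sprintf("'%s': missing required 'grid' block", path))
  g <- doc$grid
  if (is.null(g$origin) || is.null(g$spacing) || is.null(g$shape))
    stop_parse(sprintf("'%s': grid block needs origin, spacing and shape", path))
  grid <- image_grid(origin = unlist(g$origin), spacing = unlist(g$spacing),
                     shape = unlist(g$shape))
  structs <- lapply(doc$structures, function(s) {
    if (is.null(s$name))
      stop_parse(sprintf("'%s': structure without a name", path))
    role <- if (is.null(s$role)) "analysed" else s$role
    slices <- lapply(s$slices, function(polys) {
      lapply(polys, function(poly) {
        do.call(rbind, lapply(poly, function(pt) as.numeric(unlist(pt))))
      })
    })
    names(slices) <- names(s$slices)
    structure_contours(s$name, slices, role = role)
  })
  structure(list(structures = structs, grid = grid), class = "contour_set")
}

#' Write a contour file
#'
#' Writes structures and grid to the JSON contour format at full floating
#' point precision, so that `read_contours(write_contours(...))` reproduces
#' vertices exactly.
#'
#' @param structures list of [structure_contours()], or a `contour_set`.
#' @param grid an [image_grid()]; ignored if `structures` is a `contour_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(structures, grid = NULL, path) {
  if (inherits(structures, "contour_set")) {
    grid <- structures$grid
    structures <- structures$structures
  }
  if (inherits(structures, "structure_contours")) structures <- list(structures)
  if (is.null(grid))
    stop_config("write_contours needs a grid")
  doc <- list(
    grid = list(origin = grid$origin, spacing = grid$spacing,
                shape = grid$shape),
    structures = lapply(structures, function(s) {
      list(name = jsonlite::unbox(s$name),
           role = jsonlite::unbox(s$role),
           slices = lapply(s$slices, function(polys) {
             lapply(polys, function(v) {
               lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
             })
           }))
    }))
  # 17 significant digits: lossless round trip for IEEE doubles
  txt <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = FALSE,
                          null = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_config(sprintf("cannot write contour file '%s'", path))
  invisible(path)
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set: %d structure(s) on a %d x %d x %d grid>\n",
              length(x$structures), x$grid$shape[1], x$grid$shape[2],
              x$grid$shape[3]))
  for (s in x$structures) print(s)
  invisible(x)
}
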