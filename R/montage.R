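# Electrode montage as a 2-D grid ------------------------------------------
#
# The surface-Laplacian mask and the informative-channel score both assume
# that scalp electrodes sit on a rectangular row/column grid (rows are the
# 10-10 coronal lines Fp..O, columns the lateral positions 7,5,3,1,z,2,4,6,8).
# A montage_grid stores the label <-> (row, col) bijection; channels with no
# natural grid position (mastoids, EOG) are simply left off the grid.

#' Build an electrode grid from a layout table
#'
#' @param layout a data.frame (or list of 3-element vectors) with columns
#'   `label`, `row`, `col`; rows and columns are 0-based integers.
#' @return an object of class `montage_grid` with fields `label_to_cell`
#'   (named list of `c(row, col)`), `cells` (matrix of labels, `""` = empty),
#'   `n_rows`, `n_cols`.
#' @examples
#' g <- build_grid(data.frame(label = c("A1", "A2"), row = 0, col = 0:1))
#' neighbors(g, "A1", d = 1)
#' @export
build_grid <- function(layout) {
  if (!is.data.frame(layout)) {
    layout <- as.data.frame(do.call(rbind, lapply(layout, function(x) {
      data.frame(label = as.character(x[[1]]),
                 row = as.integer(x[[2]]), col = as.integer(x[[3]]))
    })))
  }
  stopifnot(all(c("label", "row", "col") %in% names(layout)))
  label <- as.character(layout$label)
  row <- as.integer(layout$row)
  col <- as.integer(layout$col)
  if (anyNA(row) || anyNA(col) || any(row < 0) || any(col < 0)) {
    stop("layout rows/columns must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(label)) {
    stop("duplicate electrode label in layout: ",
         paste(unique(label[duplicated(label)]), collapse = ", "), call. = FALSE)
  }
  cell_key <- paste(row, col)
  if (anyDuplicated(cell_key)) {
    stop("two electrodes share a grid cell: ",
         paste(label[cell_key %in% cell_key[duplicated(cell_key)]], collapse = ", "),
         call. = FALSE)
  }
  n_rows <- max(row) + 1L
  n_cols <- max(col) + 1L
  cells <- matrix("", n_rows, n_cols)
  cells[cbind(row + 1L, col + 1L)] <- label
  label_to_cell <- stats::setNames(
    lapply(seq_along(label), function(i) c(row = row[i], col = col[i])), label)
  structure(list(label_to_cell = label_to_cell, cells = cells,
                 n_rows = n_rows, n_cols = n_cols),
            class = "montage_grid")
}

#' @export
print.montage_grid <- function(x, ...) {
  cat(sprintf("<montage_grid> %d electrodes on a %d x %d grid\n",
              length(x$label_to_cell), x$n_rows, x$n_cols))
  invisible(x)
}

#' Default 60-channel 10-10 layout
#'
#' Rows (anterior to posterior): Fp, AF, F, FC, C, CP, P, PO, O; columns
#' ordered 7,5,3,1,z,2,4,6,8.  Fp and O electrodes are placed over the
#' "3"/"z"/"4" columns so that the frontal/central candidate mask centers
#' (F3, Fz, F4, FC3, FCz, FC4, C3, CPz, C4) admit small masks and F3/F4/C3
#' admit large masks.  The clinical cap of any given dataset is not published
#' with the recordings this layout stands in for; override it via
#' [build_grid()] or [read_layout()] to match a real cap.
#'
#' @return a `montage_grid` with 60 electrodes.
#' @export
default_layout_60 <- function() {
  # column index within the 9-wide grid for lateral positions
  cpos <- c("7" = 0L, "5" = 1L, "3" = 2L, "1" = 3L, "z" = 4L,
            "2" = 5L, "4" = 6L, "6" = 7L, "8" = 8L)
  full_row <- function(prefix, row, sides = names(cpos)) {
    data.frame(label = paste0(prefix, sides), row = row, col = cpos[sides],
               row.names = NULL)
  }
  layout <- rbind(
    data.frame(label = c("Fp1", "Fp2"), row = 0L, col = cpos[c("3", "4")]),
    data.frame(label = c("AF7", "AF3", "AFz", "AF4", "AF8"), row = 1L,
               col = cpos[c("7", "3", "z", "4", "8")]),
    full_row("F", 2L),
    data.frame(label = c("FT7", paste0("FC", c("5", "3", "1", "z", "2", "4", "6")), "FT8"),
               row = 3L, col = cpos),
    data.frame(label = c("T7", paste0("C", c("5", "3", "1", "z", "2", "4", "6")), "T8"),
               row = 4L, col = cpos),
    data.frame(label = c("TP7", paste0("CP", c("5", "3", "1", "z", "2", "4", "6")), "TP8"),
               row = 5L, col = cpos),
    full_row("P", 6L),
    data.frame(label = c("PO7", "PO3", "POz", "PO4", "PO8"), row = 7L,
               col = cpos[c("7", "3", "z", "4", "8")]),
    data.frame(label = c("O1", "Oz", "O2"), row = 8L, col = cpos[c("3", "z", "4")])
  )
  build_grid(layout)
}

#' Read a layout file
#'
#' Plain-text table `label<TAB>row<TAB>col`, one electrode per line,
#' 0-based integer coordinates.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a `montage_grid`.
#' @export
read_layout <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                           col.names = c("label", "row", "col"),
                           colClasses = c("character", "integer", "integer"))
  build_grid(tab)
}

grid_cell <- function(grid, label) {
  cell <- grid$label_to_cell[[label]]
  if (is.null(cell)) {
    stop("electrode '", label, "' is not on the montage grid", call. = FALSE)
  }
  cell
}

#' Four-neighborhood of a grid electrode
#'
#' Returns the electrodes `d` grid steps above, left of, below and right of
#' `center` — the mask support of the discrete Laplacian.  `d = 1` is the
#' small mask (immediate neighbors), `d = 2` the large mask.
#'
#' @param grid a `montage_grid`.
#' @param center electrode label; must be on the grid.
#' @param d neighbor distance, 1 or 2.
#' @return a list with `labels` (named character vector, NA where a neighbor
#'   cell is empty or off-grid), `missing` (names of the absent directions)
#'   and `complete` (TRUE iff all four neighbors exist).
#' @export
neighbors <- function(grid, center, d = 1L) {
  stopifnot(d %in% c(1L, 2L))
  cell <- grid_cell(grid, center)
  offs <- list(above = c(-d, 0L), left = c(0L, -d),
               below = c(d, 0L), right = c(0L, d))
  labels <- vapply(offs, function(o) {
    r <- cell[1] + o[1]
    c <- cell[2] + o[2]
    if (r < 0 || c < 0 || r >= grid$n_rows || c >= grid$n_cols) return(NA_character_)
    lab <- grid$cells[r + 1L, c + 1L]
    if (!nzchar(lab)) NA_character_ else lab
  }, character(1))
  list(labels = labels, missing = names(labels)[is.na(labels)],
       complete = !anyNA(labels))
}
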