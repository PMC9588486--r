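## Small internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
## state afterwards.  All exported stochastic entry points route their
## randomness through this, so a seed fully determines their output.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write a parameter set as flat JSON
#'
#' @param params named numeric vector or parameter object.
#' @param path output file.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a point cloud as CSV
#'
#' @param cloud numeric matrix with named columns.
#' @param path output file.
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a barcode list as CSV
#'
#' Columns `dim,birth,death`, with the literal `inf` for essential
#' classes.
#'
#' @param barcodes list of per-dimension barcode data frames.
#' @param path output file.
#' @export
write_barcodes_csv <- function(barcodes, path) {
  rows <- do.call(rbind, lapply(seq_along(barcodes), function(i) {
    b <- barcodes[[i]]
    if (nrow(b) == 0) return(NULL)
    data.frame(dim = i - 1L, birth = b$birth,
               death = ifelse(is.infinite(b$death), "inf",
                              format(b$death, digits = 12)))
  }))
  if (is.null(rows))
    rows <- data.frame(dim = integer(0), birth = numeric(0),
                       death = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
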