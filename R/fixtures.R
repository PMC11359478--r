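#' Packaged example judgments over four climate hazards
#'
#' A synthetic single-expert judgment set over the four demonstration
#' hazards (warming; flooding, storms and cyclones; drought; sea level
#' rise), reconstructed so that its geometric-mean weights round to the
#' published walk-through values (0.10, 0.65, 0.19, 0.06). The
#' reconstruction is unique on the odd Saaty scale but remains a
#' reconstruction, not an elicited matrix.
#'
#' @return `example_hazard_judgments()` returns the judgment data frame;
#'   `example_hazard_matrix()` the corresponding 4x4 [pcmatrix()].
#' @export
#' @examples
#' m <- example_hazard_matrix()
#' round(geometric_mean_weights(m), 2)
example_hazard_judgments <- function() {
  read_judgments(system.file("extdata", "hazard_judgments.csv",
                             package = "zoonoprior"))
}

#' @rdname example_hazard_judgments
#' @export
example_hazard_matrix <- function() {
  matrix_from_judgments(
    example_hazard_judgments(),
    c("warming", "flooding", "drought", "sea_level_rise"),
    set_id = "hazard"
  )
}
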