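# Frame-to-frame linking as an exact linear assignment problem with
# birth/death alternatives (augmented square cost matrix).

#' Default linking weights and gates
#'
#' Cost of matching detection `i` to `j`:
#' `w_pos * d(i,j)^2 + w_int * |I_i - I_j| / (I_i + I_j)`; matches farther
#' apart than `gate` are forbidden, and every detection can instead take a
#' fixed-cost birth/death alternative (default `gate^2 * w_pos`).
#'
#' @param w_pos Weight of the squared centroid distance (px^-2).
#' @param w_int Weight of the normalized intensity difference.
#' @param gate Maximum linking distance (px).
#' @param birth_cost,death_cost Fixed costs of an unmatched appearance /
#'   disappearance; default `gate^2 * w_pos`.
#' @return A `"link_params"` list.
#' @export
link_params <- function(w_pos = 1, w_int = 10, gate = 30,
                        birth_cost = NULL, death_cost = NULL) {
  if (w_pos < 0 || w_int < 0 || gate <= 0) {
    stop("link_params(): weights must be >= 0 and gate > 0", call. = FALSE)
  }
  if (is.null(birth_cost)) birth_cost <- gate^2 * w_pos
  if (is.null(death_cost)) death_cost <- gate^2 * w_pos
  structure(list(w_pos = w_pos, w_int = w_int, gate = gate,
                 birth_cost = birth_cost, death_cost = death_cost),
            class = "link_params")
}

# Pairwise linking cost matrix (n1 x n2); Inf where the gate forbids a match.
link_cost_matrix <- function(det1, det2, params) {
  n1 <- nrow(det1); n2 <- nrow(det2)
  dx <- outer(det1$x_px, det2$x_px, "-")
  dy <- outer(det1$y_px, det2$y_px, "-")
  d2 <- dx * dx + dy * dy
  cost <- params$w_pos * d2
  if (params$w_int > 0) {
    si <- outer(det1$intensity, det2$intensity, "+")
    di <- abs(outer(det1$intensity, det2$intensity, "-"))
    cost <- cost + params$w_int * ifelse(si > 0, di / si, 0)
  }
  cost[d2 > params$gate^2] <- Inf
  matrix(cost, n1, n2)
}

#' Optimally link two frames of detections
#'
#' Solves, exactly, the assignment problem that minimizes the total cost of
#' matched pairs plus fixed birth/death costs for unmatched detections (see
#' [link_params()] for the cost form). The problem is posed as a square
#' augmented matrix (real-vs-real block, diagonal death and birth blocks, a
#' zero dummy block) and solved with the Hungarian method.
#'
#' @param det1,det2 Detection data frames from [segment_cells()] (columns
#'   `x_px`, `y_px`, `intensity`) for consecutive frames; zero-row inputs
#'   are allowed.
#' @param params A [link_params()].
#' @return A list: `matches` (data frame `i`, `j`, `cost`), `deaths`
#'   (indices into `det1`), `births` (indices into `det2`), and the total
#'   objective `cost` (matched costs + birth/death costs).
#' @export
link_frames <- function(det1, det2, params = link_params()) {
  n1 <- if (is.null(det1)) 0L else nrow(det1)
  n2 <- if (is.null(det2)) 0L else nrow(det2)
  if (n1 == 0L && n2 == 0L) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     cost = numeric()),
                deaths = integer(), births = integer(), cost = 0))
  }
  if (n1 == 0L) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     cost = numeric()),
                deaths = integer(), births = seq_len(n2),
                cost = n2 * params$birth_cost))
  }
  if (n2 == 0L) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     cost = numeric()),
                deaths = seq_len(n1), births = integer(),
                cost = n1 * params$death_cost))
  }
  cm <- link_cost_matrix(det1, det2, params)
  big <- 1e9
  n <- n1 + n2
  M <- matrix(big, n, n)
  M[seq_len(n1), seq_len(n2)] <- pmin(cm, big)
  for (i in seq_len(n1)) M[i, n2 + i] <- params$death_cost
  for (j in seq_len(n2)) M[n1 + j, j] <- params$birth_cost
  M[(n1 + 1):n, (n2 + 1):n] <- 0
  sol <- clue::solve_LSAP(M)
  assign <- as.integer(sol)
  mi <- mj <- integer(0); mc <- numeric(0)
  deaths <- integer(0); births <- integer(0)
  for (i in seq_len(n1)) {
    j <- assign[i]
    if (j <= n2 && is.finite(cm[i, j])) {
      mi <- c(mi, i); mj <- c(mj, j); mc <- c(mc, cm[i, j])
    } else {
      deaths <- c(deaths, i)
    }
  }
  births <- setdiff(seq_len(n2), mj)
  list(matches = data.frame(i = mi, j = mj, cost = mc),
       deaths = deaths, births = births,
       cost = sum(mc) + length(deaths) * params$death_cost +
         length(births) * params$birth_cost)
}
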