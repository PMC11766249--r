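# Shared fixture builders: random-but-valid landmark configurations and
# small grouped samples, all generated in code.

random_landmarks <- function() {
  # anchors spread out enough that slit endpoints never coincide
  anchors <- cbind(c(0, 25, 50, 130, 155, 180) + runif(6, -5, 5),
                   runif(6, -5, 5))
  len <- runif(6, 30, 60)
  ang <- runif(6, 20, 160) * pi / 180
  pts <- matrix(NA_real_, 12, 2)
  for (k in 1:6) {
    pts[2 * k - 1, ] <- anchors[k, ]
    pts[2 * k, ] <- anchors[k, ] + len[k] * c(cos(ang[k]), sin(ang[k]))
  }
  colnames(pts) <- c("x", "y")
  pts
}

specimen_row <- function(id, lm = random_landmarks(), papillae = 0,
                         operculum = 1, labellum = FALSE,
                         species = "Phormia regina") {
  row <- data.frame(specimen_id = id, species = species,
                    papillae = papillae, operculum = operculum,
                    labellum = labellum, stringsAsFactors = FALSE)
  for (k in 1:12) {
    row[[paste0("x", k)]] <- if (is.null(lm)) NA_real_ else lm[k, 1]
    row[[paste0("y", k)]] <- if (is.null(lm)) NA_real_ else lm[k, 2]
  }
  row
}

random_specimen_table <- function(n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    specimen_row(sprintf("sp%03d", i), papillae = sample(0:1, 1))
  }))
  as_specimen_table(tab)
}

random_grouped_sample <- function(n_per = 8, g = 3, p = 3) {
  groups <- factor(rep(LETTERS[seq_len(g)], each = n_per))
  x <- matrix(rnorm(n_per * g * p), ncol = p)
  x <- x + 2 * matrix(rep(seq_len(g), each = n_per), nrow(x), p)
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, groups = groups)
}

rigid_transform <- function(pts, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  swept <- pts %*% t(R)
  sweep(swept, 2, shift, "+")
}
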