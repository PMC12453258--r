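# Leave-one-out spatial assignment: an individual's masked origin is
# re-estimated by moving it to a placeholder deme at the habitat centre and
# fitting the source of a long-range edge into that placeholder.

# Grid node nearest the centroid of all node coordinates (ties: lowest id).
placeholder_node <- function(grid) {
  cen <- colMeans(grid$node_coords)
  d <- geosphere::distHaversine(cen, grid$node_coords)
  which(d <= min(d) + 1e-9)[1]
}

#' Predict the origin of one individual
#'
#' The individual's coordinates are replaced by a placeholder deme (the grid
#' node nearest the habitat centroid), distances are recomputed, and a
#' long-range edge into the placeholder is fitted (pre-fit scan over the grid
#' plus joint re-fit). The MLE source node is the predicted origin.
#'
#' @param individual row index into `genotypes`.
#' @param genotypes n x p dosage matrix.
#' @param sample_coords n x 2 true coordinates (used for the other samples).
#' @param grid a `spatial_grid`.
#' @param surface baseline `migration_surface` fitted to the full data; its
#'   weights are reused. Variances for newly observed demes (the placeholder)
#'   are kriged from the surface.
#' @param refit if TRUE, the baseline surface is refitted on the masked data
#'   (slower); penalties are taken from `surface`.
#' @param joint if TRUE (default) run the joint re-fit; otherwise the scan
#'   argmax is the prediction.
#' @param placeholder optional node id overriding the centroid rule.
#' @return list(pred_node, pred_lonlat, c_hat, loglik, scan).
#' @export
assign_individual <- function(individual, genotypes, sample_coords, grid,
                              surface, refit = FALSE, joint = TRUE,
                              placeholder = NULL) {
  n <- nrow(genotypes)
  if (individual < 1 || individual > n) stop("individual out of range")
  ph <- if (is.null(placeholder)) placeholder_node(grid) else placeholder
  coords_m <- as.matrix(sample_coords)
  coords_m[individual, ] <- grid$node_coords[ph, ]
  asg <- assign_samples(coords_m, grid)
  if (length(asg$observed_demes) < 3)
    stop("masking leaves fewer than 3 observed demes")
  bundle <- observed_genetic_distances(genotypes, asg)
  p <- bundle$p

  if (refit) {
    fit <- fit_baseline(bundle, grid, asg, surface$lambda_w, surface$lambda_q)
    sfc <- fit$surface
  } else {
    # reuse weights; map variances onto the masked observed set, kriging any
    # deme not in the original fit
    demes_m <- asg$observed_demes
    q_m <- numeric(length(demes_m))
    known <- match(demes_m, surface$demes)
    Lp <- surface_pinv(surface)
    dLp <- diag(Lp)
    Ro <- outer(dLp[surface$demes], dLp[surface$demes], "+") -
      2 * Lp[surface$demes, surface$demes]
    diag(Ro) <- 0
    vg <- fit_variogram(surface$q, Ro)
    for (i in seq_along(demes_m)) {
      if (!is.na(known[i])) q_m[i] <- surface$q[known[i]]
      else {
        r <- dLp[demes_m[i]] + dLp[surface$demes] - 2 * Lp[demes_m[i], surface$demes]
        q_m[i] <- krige_variance(vg, r, surface$q)
      }
    }
    sfc <- new_migration_surface(grid, demes_m, surface$w, q_m,
                                 surface$lambda_w, surface$lambda_q)
  }
  deme_ph <- asg$deme_of_sample[individual]
  scan <- prefit_scan(deme_ph, bundle$D_hat, sfc, p)
  if (joint) {
    edge <- joint_refit(deme_ph, scan, bundle$D_hat, sfc, p)
    pred <- edge$source
    list(pred_node = pred, pred_lonlat = as.numeric(grid$node_coords[pred, ]),
         c_hat = edge$c, loglik = edge$loglik, scan = scan)
  } else {
    pred <- scan$node[which.max(scan$loglik)]
    list(pred_node = pred, pred_lonlat = as.numeric(grid$node_coords[pred, ]),
         c_hat = scan$c_hat[which.max(scan$loglik)],
         loglik = max(scan$loglik), scan = scan)
  }
}

#' Leave-one-out assignment of every individual
#'
#' @inheritParams assign_individual
#' @param ... passed to [assign_individual()].
#' @return data frame (sample, true_lon, true_lat, pred_lon, pred_lat,
#'   error_km).
#' @export
assign_loo <- function(genotypes, sample_coords, grid, surface, ...) {
  n <- nrow(genotypes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- tryCatch(assign_individual(i, genotypes, sample_coords, grid,
                                    surface, ...),
                  error = function(e) NULL)
    out[[i]] <- if (is.null(a)) {
      data.frame(sample = i, true_lon = sample_coords[i, 1],
                 true_lat = sample_coords[i, 2], pred_lon = NA, pred_lat = NA,
                 error_km = NA)
    } else {
      data.frame(sample = i, true_lon = sample_coords[i, 1],
                 true_lat = sample_coords[i, 2], pred_lon = a$pred_lonlat[1],
                 pred_lat = a$pred_lonlat[2],
                 error_km = geosphere::distHaversine(
                   sample_coords[i, ], a$pred_lonlat) / 1000)
    }
  }
  do.call(rbind, out)
}

#' Great-circle assignment errors
#'
#' Haversine distance in km between predicted and true locations, with the
#' median as the headline summary.
#'
#' @param predictions,truths matrices (or data frames) of (lon, lat) rows.
#' @return list(error_km, median_km, mean_km).
#' @export
assignment_report <- function(predictions, truths) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (nrow(predictions) != nrow(truths)) stop("prediction/truth length mismatch")
  err <- geosphere::distHaversine(predictions, truths) / 1000
  list(error_km = err, median_km = stats::median(err), mean_km = mean(err))
}
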