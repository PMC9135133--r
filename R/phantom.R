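# Synthetic whole-body scintigram phantoms. A procedural anatomy template
# (body silhouette, skeleton, joint sites, neck box) defines expected count
# rates; class-conditional lesion placement plus Poisson counting noise
# yields labelled images with the discriminative structure the classifier
# must exploit: normal = no lesion, metastasis = hotspots anywhere on bone,
# arthritis = hotspots at joints (often symmetric), thyroid carcinoma = one
# hotspot at a fixed neck location. All classes share one lesion-amplitude
# distribution so intensity alone is non-discriminative between diseases.

# --- geometric primitives on the native 1024 x 256 grid ---------------------

grid_coords <- function(H = 1024L, W = 256L) {
  list(I = matrix(rep(seq_len(H), W), H, W),
       J = matrix(rep(seq_len(W), each = H), H, W))
}

ellipse_mask <- function(g, r0, c0, ra, cb) {
  ((g$I - r0) / ra)^2 + ((g$J - c0) / cb)^2 <= 1
}

# capsule: all pixels within radius r of segment (r1,c1)-(r2,c2)
capsule_mask <- function(g, r1, c1, r2, c2, r) {
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr^2 + dc^2
  t <- if (len2 == 0) 0 else
    pmin(pmax(((g$I - r1) * dr + (g$J - c1) * dc) / len2, 0), 1)
  (g$I - (r1 + t * dr))^2 + (g$J - (c1 + t * dc))^2 <= r^2
}

#' Procedural whole-body anatomy template
#'
#' Deterministic stylized anatomy on the native 1024 x 256 grid: a body
#' silhouette, a skeleton mask (skull, spine, clavicles, ribs, pelvis, arm
#' and leg long bones), 12 joint sites (6 bilateral pairs: shoulders,
#' elbows, wrists, hips, knees, ankles) and a rectangular neck window for
#' the thyroid region, plus baseline expected count rates for soft tissue
#' and bone.
#'
#' @param b_body Expected counts/pixel in soft tissue (default 5).
#' @param b_bone Expected counts/pixel in bone (default 20); must exceed
#'   `b_body`.
#' @return An object of class `"anatomy_template"` with elements `body_mask`,
#'   `bone_mask` (logical 1024 x 256), `joint_sites` (12 x 2 matrix of
#'   (row, col) with rownames like `"shoulder_L"`), `neck_box`
#'   (`c(rmin, rmax, cmin, cmax)`), `b_body`, `b_bone`.
#' @export
make_template <- function(b_body = 5, b_bone = 20) {
  stopifnot(b_bone > b_body, b_body > 0)
  g <- grid_coords()
  mid <- 128.5

  body <- ellipse_mask(g, 70, mid, 58, 42) |               # head
    (g$I >= 108 & g$I <= 175 & abs(g$J - mid) <= 20) |     # neck
    ellipse_mask(g, 360, mid, 210, 72) |                   # torso
    ellipse_mask(g, 520, mid, 60, 60)                      # pelvis block
  arm_j <- list(sh = c(195, 57), el = c(305, 78), wr = c(425, 92))
  leg_j <- list(hip = c(530, 31), kn = c(715, 25), an = c(930, 20))
  for (s in c(-1, 1)) {
    body <- body |
      capsule_mask(g, 195, mid + s * 57, 305, mid + s * 78, 15) |
      capsule_mask(g, 305, mid + s * 78, 425, mid + s * 92, 13) |
      capsule_mask(g, 530, mid + s * 31, 715, mid + s * 25, 22) |
      capsule_mask(g, 715, mid + s * 25, 930, mid + s * 20, 18) |
      capsule_mask(g, 930, mid + s * 20, 955, mid + s * 32, 12)
  }

  bone <- ellipse_mask(g, 70, mid, 44, 31) |               # skull
    capsule_mask(g, 112, mid, 545, mid, 8) |               # spine
    (ellipse_mask(g, 520, mid, 42, 40) &
       !ellipse_mask(g, 520, mid, 26, 25))                 # pelvic ring
  for (rr in c(215, 255, 295, 335)) {                      # rib pairs
    bone <- bone |
      capsule_mask(g, rr, mid, rr + 28, mid - 58, 4) |
      capsule_mask(g, rr, mid, rr + 28, mid + 58, 4)
  }
  for (s in c(-1, 1)) {
    bone <- bone |
      capsule_mask(g, 188, mid + s * 12, 195, mid + s * 57, 5) | # clavicle
      capsule_mask(g, 195, mid + s * 57, 305, mid + s * 78, 7) | # humerus
      capsule_mask(g, 305, mid + s * 78, 425, mid + s * 92, 6) | # forearm
      capsule_mask(g, 530, mid + s * 31, 715, mid + s * 25, 9) | # femur
      capsule_mask(g, 715, mid + s * 25, 930, mid + s * 20, 8)   # tibia
  }
  bone <- bone & body

  sides <- c(-1, 1)
  joints <- rbind(
    shoulder = c(195, 57), elbow = c(305, 78), wrist = c(425, 92),
    hip = c(530, 31), knee = c(715, 25), ankle = c(930, 20))
  joint_sites <- do.call(rbind, lapply(rownames(joints), function(nm) {
    out <- rbind(c(joints[nm, 1], mid - joints[nm, 2]),
                 c(joints[nm, 1], mid + joints[nm, 2]))
    rownames(out) <- paste0(nm, c("_L", "_R"))
    out
  }))
  colnames(joint_sites) <- c("row", "col")

  structure(list(body_mask = body, bone_mask = bone,
                 joint_sites = joint_sites,
                 # thyroid bed: ~2.7 cm square at 2.26 mm/px, on the midline
                 neck_box = c(rmin = 131, rmax = 142, cmin = 123, cmax = 134),
                 b_body = b_body, b_bone = b_bone),
            class = "anatomy_template")
}

#' Phantom cohort configuration
#'
#' Class-conditional lesion placement, intensity, artifact and noise
#' parameters for the synthetic cohort. Lesions are isotropic Gaussian
#' bumps of amplitude `a * b_bone` with `a` uniform on `a_range`
#' (`a_range[1] > 1`: lesions are hot). The same amplitude distribution is
#' shared by all diseased classes.
#'
#' @param n_per_class Patients per class.
#' @param a_range Lesion amplitude multiplier range over bone baseline.
#' @param sigma_lesion Lesion Gaussian sigma in native pixels.
#' @param met_sites Range (min, max) of metastatic lesion counts.
#' @param arthritis_sites Range (min, max) of affected joints.
#' @param symmetry_prob Probability that an arthritic joint's mirror partner
#'   is also affected.
#' @param p_artifact Probability of a physiologic artifact (injection-site
#'   uptake at a wrist/elbow, or bladder activity at the pelvis midline) in
#'   any image regardless of class.
#' @param attenuation Multiplicative factor applied to the posterior view.
#' @param p_missing Probability that a patient's posterior view was not
#'   recorded.
#' @param template An [make_template()] anatomy.
#' @param seed Cohort RNG seed.
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(n_per_class = 10L, a_range = c(2, 4),
                           sigma_lesion = 4, met_sites = c(1L, 5L),
                           arthritis_sites = c(1L, 3L), symmetry_prob = 0.6,
                           p_artifact = 0.3, attenuation = 0.9,
                           p_missing = 0.1, template = make_template(),
                           seed = 1L) {
  stopifnot(a_range[1] > 1, a_range[2] >= a_range[1],
            p_artifact >= 0, p_artifact <= 1,
            p_missing >= 0, p_missing <= 1,
            symmetry_prob >= 0, symmetry_prob <= 1,
            met_sites[1] >= 1, met_sites[2] >= met_sites[1],
            arthritis_sites[2] >= arthritis_sites[1],
            sigma_lesion > 0, attenuation > 0, n_per_class >= 1)
  structure(list(n_per_class = as.integer(n_per_class), a_range = a_range,
                 sigma_lesion = sigma_lesion,
                 met_sites = as.integer(met_sites),
                 arthritis_sites = as.integer(arthritis_sites),
                 symmetry_prob = symmetry_prob, p_artifact = p_artifact,
                 attenuation = attenuation, p_missing = p_missing,
                 template = template, seed = as.integer(seed)),
            class = "phantom_config")
}

runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# class-conditional lesion placement; returns matrix (row, col, amplitude)
place_lesions <- function(label, config) {
  tpl <- config$template
  amp <- function(n) stats::runif(n, config$a_range[1], config$a_range[2])
  if (label == "normal") {
    sites <- matrix(numeric(0), 0, 2)
  } else if (label == "metastasis") {
    k <- runif_int(config$met_sites[1], config$met_sites[2])
    on_bone <- which(tpl$bone_mask)
    pick <- on_bone[sample.int(length(on_bone), k)]
    sites <- cbind((pick - 1L) %% nrow(tpl$bone_mask) + 1L,
                   (pick - 1L) %/% nrow(tpl$bone_mask) + 1L)
  } else if (label == "arthritis") {
    k <- runif_int(config$arthritis_sites[1], config$arthritis_sites[2])
    chosen <- sample.int(nrow(tpl$joint_sites), k)
    for (j in chosen) {
      partner <- if (j %% 2L == 1L) j + 1L else j - 1L
      if (!(partner %in% chosen) && stats::runif(1) < config$symmetry_prob)
        chosen <- c(chosen, partner)
    }
    sites <- tpl$joint_sites[chosen, , drop = FALSE]
  } else if (label == "thyroid_carcinoma") {
    nb <- tpl$neck_box
    sites <- cbind(runif_int(nb["rmin"], nb["rmax"]),
                   runif_int(nb["cmin"], nb["cmax"]))
  } else stop("invalid class label: ", label)
  cbind(sites, if (nrow(sites)) amp(nrow(sites)) else numeric(0))
}

add_bump <- function(expected, row, col, height, sigma) {
  H <- nrow(expected); W <- ncol(expected)
  half <- ceiling(4 * sigma)
  ri <- max(1, round(row) - half):min(H, round(row) + half)
  cj <- max(1, round(col) - half):min(W, round(col) + half)
  bump <- outer(exp(-(ri - row)^2 / (2 * sigma^2)),
                exp(-(cj - col)^2 / (2 * sigma^2))) * height
  expected[ri, cj] <- expected[ri, cj] + bump
  expected
}

# expected-count map for the anterior view, before noise
expected_map <- function(lesions, config) {
  tpl <- config$template
  e <- tpl$b_body * tpl$body_mask +
    (tpl$b_bone - tpl$b_body) * tpl$bone_mask
  for (i in seq_len(nrow(lesions)))
    e <- add_bump(e, lesions[i, 1], lesions[i, 2],
                  lesions[i, 3] * tpl$b_bone, config$sigma_lesion)
  if (stats::runif(1) < config$p_artifact) {
    a <- stats::runif(1, config$a_range[1], config$a_range[2]) * tpl$b_bone
    kind <- sample.int(2L, 1L)
    if (kind == 1L) { # injection-site uptake at a random wrist or elbow
      cand <- grep("wrist|elbow", rownames(tpl$joint_sites))
      site <- tpl$joint_sites[cand[sample.int(length(cand), 1L)], ]
      e <- add_bump(e, site[1], site[2], a, config$sigma_lesion)
    } else { # bladder activity, pelvis midline
      e <- add_bump(e, 555, 128.5, a, 1.5 * config$sigma_lesion)
    }
  }
  e
}

render_view <- function(expected, view, label, patient_id, config) {
  e <- if (view == "posterior")
    config$attenuation * expected[, ncol(expected):1] else expected
  counts <- pmin(stats::rpois(length(e), as.vector(e)), 65535L)
  scinti_image(matrix(as.integer(counts), nrow(e), ncol(e)),
               patient_id = patient_id, view = view, label = label,
               provenance = "synthetic")
}

lesion_annotation <- function(image_ref, lesions, label, config) {
  sigma <- config$sigma_lesion
  regions <- lapply(seq_len(nrow(lesions)), function(i) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    # LabelMe points are (x, y) = (col, row)
    list(points = cbind(lesions[i, 2] + 2 * sigma * cos(th),
                        lesions[i, 1] + 2 * sigma * sin(th)),
         code = label)
  })
  annotation(image_ref, regions,
             annotator_votes = if (nrow(lesions) > 0) 3L else 0L)
}

#' Generate one labelled phantom view
#'
#' Draws class-conditional lesion placements, composes the expected-count
#' map (baseline anatomy + Gaussian lesion bumps + occasional artifacts) and
#' samples Poisson counts. Deterministic given the R RNG state.
#'
#' @param label One of [class_labels()].
#' @param patient_id Patient identifier for the image.
#' @param view `"anterior"` or `"posterior"`.
#' @param config A [phantom_config()].
#' @return List with `image` (a [scinti_image()]) and `annotation`
#'   (ground-truth lesion polygons).
#' @export
generate_image <- function(label, patient_id, view = "anterior", config) {
  label <- match.arg(label, class_labels())
  lesions <- place_lesions(label, config)
  e <- expected_map(lesions, config)
  img <- render_view(e, view, label, patient_id, config)
  list(image = img,
       annotation = lesion_annotation(paste0(patient_id, "_", view),
                                      lesions, label, config))
}

#' Generate a labelled phantom cohort
#'
#' For each synthetic patient the anterior view is always produced; the
#' posterior view (mirrored geometry, attenuated, independent Poisson noise)
#' is dropped with probability `p_missing`. Both views share the patient's
#' lesion placement, id and label. Fully reproducible given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param downscale Optional integer block-sum factor applied to every image
#'   (see [downscale_image()]).
#' @return List with `images` (list of [scinti_image()]), `manifest`
#'   (data.frame `file`, `patient_id`, `view`, `label`) and `annotations`
#'   (anterior-view ground truth per patient).
#' @export
generate_cohort <- function(config, downscale = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    images <- list()
    annotations <- list()
    rows <- list()
    pnum <- 0L
    for (label in class_labels()) {
      for (i in seq_len(config$n_per_class)) {
        pnum <- pnum + 1L
        pid <- sprintf("PH%04d", pnum)
        lesions <- place_lesions(label, config)
        e <- expected_map(lesions, config)
        views <- if (stats::runif(1) < config$p_missing) "anterior"
                 else c("anterior", "posterior")
        for (v in views) {
          img <- render_view(e, v, label, pid, config)
          if (downscale > 1L) img <- downscale_image(img, downscale)
          images[[length(images) + 1L]] <- img
          rows[[length(rows) + 1L]] <-
            data.frame(file = NA_character_, patient_id = pid, view = v,
                       label = label)
        }
        annotations[[length(annotations) + 1L]] <-
          lesion_annotation(paste0(pid, "_anterior"), lesions, label, config)
      }
    }
    list(images = images, manifest = do.call(rbind, rows),
         annotations = annotations)
  })
}

#' Write a cohort to disk as DICOM + manifest + ground truth
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest with `file` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$images)) {
    f <- file.path(dir, sprintf("%s_%s.dcm", man$patient_id[i], man$view[i]))
    write_scinti_dicom(cohort$images[[i]], f)
    man$file[i] <- f
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  write_annotations(cohort$annotations, file.path(dir, "ground_truth.json"))
  invisible(man)
}

#' Hand-crafted thyroid detector (benchmark sanity check)
#'
#' Mean count inside the neck box relative to the mean over the bone mask.
#' With default effect sizes this separates thyroid carcinoma from normal
#' scans nearly perfectly, guaranteeing the synthetic benchmark is learnable
#' before any network is involved.
#'
#' @param image A native-resolution [scinti_image()] (anterior).
#' @param template The [make_template()] used to generate it.
#' @return Ratio of neck-box mean to bone-mask mean.
#' @export
neck_uptake_ratio <- function(image, template = make_template()) {
  nb <- template$neck_box
  p <- image$pixels
  neck <- mean(p[nb["rmin"]:nb["rmax"], nb["cmin"]:nb["cmax"]])
  neck / mean(p[template$bone_mask])
}
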