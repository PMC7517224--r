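# gwcine

Unsupervised **groupwise deformable registration** of 2D dynamic image
sequences, with cardiac cine MRI as the motivating application, plus a
proof-of-concept motion-compensated compressed-sensing reconstruction.

## The problem and the method

A cine acquisition yields N frames m₁…m_N spanning one motion cycle.
Groupwise registration seeks the set of elastic transformations
T = {T₁, …, T_N}, Tₙ(x) = x + uₙ(x) on the template grid, that makes the
registered sequence mₙ(Tₙ(x)) static, by minimizing

    min_T  Σ_{x∈X} SSD(T(x)) + F(T(x)),
    SSD(T(x)) = (1/N) Σₙ ( mₙ(Tₙ(x)) − (1/N) Σₙ' mₙ'(Tₙ'(x)) )²

— the per-pixel temporal variance of the registered frames — where F
collects smoothness penalties λ₁..λ₄ (first/second-order spatial gradients
and first/second-order *circular* temporal differences of u) and a cyclic
constraint λ_c ‖(1/N) Σₙ uₙ(x)‖² enforcing that displacements sum to zero
over the closed cycle. A windowed normalized cross-correlation against the
template is available as an alternative (multimodal-ready) similarity.

Instead of solving this optimization per sequence, a small convolutional
encoder–decoder (two input channels: frame and template; two output
channels: the displacement components) is trained *unsupervised* to emit
the fields directly, with the loss above backpropagated through a
differentiable bilinear warper. The template is co-estimated: at iteration
l = 0 it is the frame minimizing the summed geodesic distance on a
residual-complexity kNN graph of frames; for l = 1..L (default L = 5) it
is the pointwise average of the just-registered frames. Training takes one
Adam step (lr 1e-4) per sequence and iteration, batch = the N frames, for
10 epochs; prediction runs the identical L+1-iteration loop without
updates. Registration quality is evaluated by SSIM of registered frames
against the final template at two distant frames (systole/diastole
analogues), with paired one-sided t- and sign tests, and the
regularization weights are chosen by greedy forward selection (the
canonical outcome: only the first-order temporal weight λ₃ = 1e-7 active).

The registered motion operator plugs into dynamic MRI reconstruction:
`min_m ½‖y − Em‖² + λ‖Φ T m‖₁` with E the frame-wise undersampled Fourier
encoding and Φ∘T the temporal total variation of the motion-compensated
sequence (one motion-estimation/compensation iteration, ADMM-style solver
with hard data consistency).

Everything is testable without clinical data through a seedable cine
phantom generator with known ground-truth periodic elastic motion.

## Worked example

```r
library(gwcine)

# a small training cohort of synthetic cine sequences with known motion
train <- lapply(1:30, function(i)
  generate_phantom(phantom_spec(seed = i))$sequence)

cfg <- gw_config(loss = loss_config(lambda3 = 1e-7),
                 net  = net_config(seed = 11), seed = 42)
fit <- train_gw(train, cfg)            # ~10 min on one CPU core

# register a held-out phantom
ph  <- generate_phantom(phantom_spec(seed = 101))
res <- register_gw(fit$network, ph$sequence, cfg)
res
#> <registration_result> 10 frames, 6 iterations, SSD 10.49 -> 7.026

round(res$ssd_trace, 3)
#> [1] 10.487  7.591  7.395  6.960  6.842  7.026

# SSIM of the two distant frames (max contraction, rest) vs the template,
# before and after registration
pair <- phantom_frame_pair(10)
tpl  <- res$final_template$image
round(sample_ssim(res, pair), 3)                       # registered
#> [1] 0.946 0.976
round(c(ssim(ph$sequence$frames[, , pair[1]], tpl),
        ssim(ph$sequence$frames[, , pair[2]], tpl)), 3) # unregistered
#> [1] 0.137 0.335

# identifiable recovered motion vs ground truth (mean endpoint error, px);
# the common-warp gauge the groupwise criterion leaves free is removed by
# projecting onto the zero-temporal-mean slice (see the vignette)
gt <- gt_registration_fields(ph)$displacements
u  <- res$fields$displacements
uz <- u - as.vector(apply(u, c(1, 2, 3), mean))
round(mean(sqrt(apply((uz - gt)^2, c(1, 2, 4), sum))), 2)
#> [1] 0.75
```

The groupwise SSD drops by about a third over the template iterations
(falling steeply for the first three updates, then flattening), the
registered distant frames become nearly indistinguishable from the
template, and the identifiable part of the recovered motion lands within a
fraction of a pixel of the generating fields.

A thin command-line interface wraps the same functions
(`inst/cli/gwcine.R phantom|template|train|register|recon`); see the
vignette `vignettes/groupwise-registration.Rmd` for the model, parameter
and design details.

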