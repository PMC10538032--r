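# zootrack

Video analysis of captive-animal behavior from fixed cameras, built on
one shared motion measure: for every frame triple (current frame `Ia`,
predecessors `Ib`, `Ic`),

```
Imov = D( E( max(|Ia − Ib| − |Ib − Ic|, 0) > τ ) )
```

— the thresholded double difference cleaned by morphological erosion
`E` and dilation `D`. Its nonzero pixels ("motion features")
concentrate on the animal's current position; their count measures
movement strength, and a stride-1 "counting box" search localizes the
densest cluster. On that core the package implements three
applications from behavioral research practice:

* **Rat behavior** — stage 1: per-frame head-pose estimation of a rat
  confined to the middle room of a three-chamber box (adaptive scene
  segmentation, two-vote head/tail disambiguation, offline resolution
  of uncertain frames); stage 2: compartment entry counts and visit
  durations once the gates open.
* **Monkey neuroscience support** — localization of the dark
  head-mounted sensor box in an unevenly lit cage (template model with
  edge-ring validation, confidence index gated at 75%) and head
  orientation from the box profile (filling-index contour selection,
  minimum-area rectangle, 1-D angle filter), with a light-on/off
  indicator.
* **Panda stress monitoring** — per-camera tracking state machines over
  four synchronized views (movement/freezing/no-information attributes,
  technician and bird handling, basin special case), fusion into a
  single trajectory by a zone hierarchy, compaction/gap/attribute/
  velocity filtering, and five-class stress labeling (running, walking
  1–3, stationary) with an episode report.

Seeded synthetic scene renderers (`render_rat_scene()`,
`render_monkey_scene()`, `render_panda_camera()`) produce ground-truthed
fixtures for all three pipelines, so everything is testable end to end
without proprietary recordings. Frames are plain numeric matrices in
`[0, 255]`; numbered PNG sequences are supported for real input.

## Worked example

Track a scripted two-minute stage-2 session and report the visits:

```r
library(zootrack)

s  <- scenario("rat2", fps = 10, duration_s = 120, seed = 101)
sc <- render_rat_scene(s)                  # frames + ground truth
res <- run_rat2_pipeline(sc$frames, fps = 10)
res$entries
#> left_cage     middle right_cage
#>         1          2          1
subset(res$visits, duration_s > 60)
#>   compartment start_frame end_frame start_s end_s duration_s
#> 2   left_cage         115       830    11.5    83       71.6
```

The script placed one 70 s left-cage visit; the tracker reports one
left-cage entry and measures its duration at 71.6 s (the scripted visit
spans 72 s of rendered frames — the 0.4 s difference is the crossing
detection). The four-camera panda analysis runs the same way from a
frame source per camera:

```r
pc  <- panda_scene_configs()
sp  <- scenario("panda", fps = 10, duration_s = 120, seed = 11)
res <- run_panda_pipeline(function(k) render_panda_camera(sp, as.integer(k)),
                          pc$cfgs, pc$thresholds, pc$vthr, fps = 10)
res$episodes[, c("class", "start_time_s", "duration_s", "camera")]
```

which prints the six scripted episodes (two dashes, three walking
segments, one basin dwell) with their times. A thin command-line front
end over `run_pipeline()` ships in `inst/cli/zootrack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/zootrack.R", package="zootrack"))')" \
  --config project.json --seed 1 --out results/
```

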