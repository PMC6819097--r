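# tonetrans

Learning, transmission and structural regularization of an artificial
melodic system in two-player signaling games — with the auditory-oddball
functional-localizer design and the resting-state-connectivity correlation
stage that link those behaviors to auditory cortex.

The package is for researchers in cultural evolution and auditory cognitive
neuroscience who want the full measurement pipeline of a melodic
signaling-game experiment as tested, reusable code: the formal behavioral
measures, the stimulus designs, a synthetic cohort generator that stands in
for human data, and the group-level statistics.

## The model in brief

Signals are five-tone sequences on the Bohlen-Pierce scale, which divides
the 3:1 tritave into 13 equal steps: a degree *n* above fundamental *k*
sounds at *F = k·3^(n/13)* (degrees {0, 4, 6, 7, 10} above 440 Hz in the
games). A signal's *contour* is its four interval directions (up / repeat /
down).

A participant learns a five-emotion code from a fixed-code confederate over
70 trials (Game 1), then transmits it over 30 trials (Game 2). From the two
game logs the package computes, per participant:

* **coordination** — mean similarity (1 − normalized Hamming distance)
  between the sender's code and the receiver's second-half mappings;
* **transmission** — similarity between the seeding code and the Game-2
  sender's modal code;
* **innovation** — within-player Hamming distance between the code learned
  as receiver and the code produced as sender;
* **asymmetry** — (S − R)/(S + R) over sender/receiver code-change counts;
* **accuracy** — correct Game-1 trials;
* **entropy** — mean Shannon entropy *H(X) = −Σ p(xᵢ) log₂ p(xᵢ)* of tone
  sequences and contours, per game, and the Game 1 → Game 2 delta as a
  regularization index;
* **interval compression ratio (ICR)** — mean absolute interval of the
  shuffled sequence (100 shuffles, or all 120 permutations exactly) over
  that of the original; values > 1 mean a bias toward small intervals.

The oddball module generates the 1260-stimulus functional-localizer stream
(80% standards, 10% contour deviants, 10% interval deviants, same-type
deviant pairs 2400–4800 ms apart) and the balanced extraction of 126
flanked standards used for GLM balancing. The neurobehavior module computes
ROI-to-ROI Fisher-z connectivity from seed time courses and correlates it
with the behavioral measures, Bonferroni-corrected at α = 0.05/7 = 0.007.

## Worked example

```r
library(tonetrans)
set.seed(2)

seed <- make_seed_codes()$A                 # seeding code, H = 1/1/.81/.81/0
p <- participant_params(ability = 0.8)      # an abler-than-average learner
g1 <- simulate_game1(p, seed)               # 70-trial learning game
learned <- modal_code(g1, "receiver", window = 36:70)
g2 <- simulate_game2(p, learned)            # 30-trial transmission game
m <- compute_measure_set(g1, g2, seed)
round(as.data.frame(m[c("coordination_tone", "transmission_tone",
                        "innovation_tone", "accuracy", "asymmetry_g2",
                        "entropy_contour_g1", "entropy_contour_g2",
                        "delta_icr")]), 3)
#>   coordination_tone transmission_tone innovation_tone accuracy asymmetry_g2
#> 1             0.919              0.76            0.24       45           -1
#>   entropy_contour_g1 entropy_contour_g2 delta_icr
#> 1              0.725                  1    -0.006
```

This participant learned most of the code (coordination 0.92, 45/70 correct
trials), transmitted it with fidelity 0.76 while changing about one position
per signal (innovation 0.24), and — as in any game against a fixed-code
sender who never adapts — the asymmetry is −1. The Game-2 contour entropy
rose from 0.725 to 1 bit: this simulated participant diversified rather
than regularized the contours.

The permutation machinery behind the ICR:

```r
as.numeric(icr(c(0, 4, 6, 7, 10), exact = TRUE))
#> [1] 1.84
```

Shuffling this ascending sequence stretches its mean interval by 84%, i.e.
the original is strongly biased toward proximal intervals.

## The analysis workflow

The `analysis/` scripts run the study-scale pipeline end to end, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 51 participants, logs + FC + spans
Rscript analysis/02_game_metrics.R      # per-participant measures, Wilcoxon
Rscript analysis/03_oddball_design.R    # 1260-trial design + balanced events
Rscript analysis/04_neurobehavior.R     # correlation table, Table-1 layout
```

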