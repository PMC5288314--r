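# Default metabolite library for 1H-NMR tissue-extract simulation.
# Chemical shifts are literature values for aqueous extracts at pH 7
# (600 MHz); they are editable simulation defaults, not measurements.
# relative_intensity is proportional to proton count of the multiplet,
# linewidth_hz is the full width at half maximum of the Lorentzian.
# reference_peak marks the well-resolved peak used for univariate tracking.
metabolites:
  - name: leucine
    base_log_concentration: 0.8
    reference_peak: 0.96
    peaks:
      - {center_ppm: 0.96, relative_intensity: 6.0, linewidth_hz: 2.0}
  - name: isoleucine
    base_log_concentration: 0.5
    reference_peak: 1.01
    peaks:
      - {center_ppm: 0.94, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 1.01, relative_intensity: 3.0, linewidth_hz: 2.0}
  - name: valine
    base_log_concentration: 0.6
    reference_peak: 1.04
    peaks:
      - {center_ppm: 0.99, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 1.04, relative_intensity: 3.0, linewidth_hz: 2.0}
  - name: 3-hydroxybutyrate
    base_log_concentration: 0.8
    reference_peak: 1.20
    peaks:
      - {center_ppm: 1.20, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 2.31, relative_intensity: 1.0, linewidth_hz: 2.2}
      - {center_ppm: 4.16, relative_intensity: 1.0, linewidth_hz: 2.2}
  - name: lactate
    base_log_concentration: 2.0
    reference_peak: 1.33
    peaks:
      - {center_ppm: 1.33, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 4.11, relative_intensity: 1.0, linewidth_hz: 2.2}
  - name: alanine
    base_log_concentration: 1.2
    reference_peak: 1.48
    peaks:
      - {center_ppm: 1.48, relative_intensity: 3.0, linewidth_hz: 2.0}
  - name: acetate
    base_log_concentration: 0.8
    reference_peak: 1.92
    peaks:
      - {center_ppm: 1.92, relative_intensity: 3.0, linewidth_hz: 2.0}
  - name: propionate
    base_log_concentration: 0.2
    reference_peak: 2.18
    peaks:
      - {center_ppm: 1.06, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 2.18, relative_intensity: 2.0, linewidth_hz: 2.2}
  - name: glutamate
    base_log_concentration: 1.4
    reference_peak: 2.35
    peaks:
      - {center_ppm: 2.05, relative_intensity: 2.0, linewidth_hz: 2.5}
      - {center_ppm: 2.35, relative_intensity: 2.0, linewidth_hz: 2.5}
  - name: glutamine
    base_log_concentration: 1.2
    reference_peak: 2.45
    peaks:
      - {center_ppm: 2.14, relative_intensity: 2.0, linewidth_hz: 2.5}
      - {center_ppm: 2.45, relative_intensity: 2.0, linewidth_hz: 2.5}
  - name: succinate
    base_log_concentration: 0.5
    reference_peak: 2.41
    peaks:
      - {center_ppm: 2.41, relative_intensity: 4.0, linewidth_hz: 2.0}
  - name: citrate
    base_log_concentration: 0.7
    reference_peak: 2.54
    peaks:
      - {center_ppm: 2.54, relative_intensity: 2.0, linewidth_hz: 2.2}
      - {center_ppm: 2.66, relative_intensity: 2.0, linewidth_hz: 2.2}
  - name: aspartate
    base_log_concentration: 0.6
    reference_peak: 2.81
    peaks:
      - {center_ppm: 2.68, relative_intensity: 1.0, linewidth_hz: 2.5}
      - {center_ppm: 2.81, relative_intensity: 1.0, linewidth_hz: 2.5}
  - name: creatine
    base_log_concentration: 1.5
    reference_peak: 3.04
    peaks:
      - {center_ppm: 3.04, relative_intensity: 3.0, linewidth_hz: 2.0}
      - {center_ppm: 3.93, relative_intensity: 2.0, linewidth_hz: 2.0}
  - name: choline
    base_log_concentration: 0.7
    reference_peak: 3.20
    peaks:
      - {center_ppm: 3.20, relative_intensity: 9.0, linewidth_hz: 2.0}
  - name: phosphocholine
    base_log_concentration: 1.0
    reference_peak: 3.22
    peaks:
      - {center_ppm: 3.22, relative_intensity: 9.0, linewidth_hz: 2.0}
  - name: glycerophosphocholine
    base_log_concentration: 1.0
    reference_peak: 3.23
    peaks:
      - {center_ppm: 3.23, relative_intensity: 9.0, linewidth_hz: 2.0}
  - name: taurine
    base_log_concentration: 1.6
    reference_peak: 3.42
    peaks:
      - {center_ppm: 3.26, relative_intensity: 2.0, linewidth_hz: 2.2}
      - {center_ppm: 3.42, relative_intensity: 2.0, linewidth_hz: 2.2}
  - name: myoinositol
    base_log_concentration: 1.5
    reference_peak: 4.06
    peaks:
      - {center_ppm: 3.28, relative_intensity: 1.0, linewidth_hz: 2.2}
      - {center_ppm: 3.53, relative_intensity: 2.0, linewidth_hz: 2.2}
      - {center_ppm: 3.62, relative_intensity: 2.0, linewidth_hz: 2.2}
      - {center_ppm: 4.06, relative_intensity: 1.0, linewidth_hz: 2.2}
  - name: glycine
    base_log_concentration: 1.2
    reference_peak: 3.56
    peaks:
      - {center_ppm: 3.56, relative_intensity: 2.0, linewidth_hz: 2.0}
  - name: fumarate
    base_log_concentration: -0.5
    reference_peak: 6.52
    peaks:
      - {center_ppm: 6.52, relative_intensity: 2.0, linewidth_hz: 2.0}
  - name: inosine
    base_log_concentration: 0.3
    reference_peak: 8.34
    peaks:
      - {center_ppm: 6.10, relative_intensity: 1.0, linewidth_hz: 2.2}
      - {center_ppm: 8.24, relative_intensity: 1.0, linewidth_hz: 2.0}
      - {center_ppm: 8.34, relative_intensity: 1.0, linewidth_hz: 2.0}
  - name: hypoxanthine
    base_log_concentration: 0.3
    reference_peak: 8.19
    peaks:
      - {center_ppm: 8.19, relative_intensity: 1.0, linewidth_hz: 2.0}
      - {center_ppm: 8.21, relative_intensity: 1.0, linewidth_hz: 2.0}
  - name: ADP
    base_log_concentration: 0.5
    reference_peak: 8.53
    peaks:
      - {center_ppm: 6.14, relative_intensity: 1.0, linewidth_hz: 2.2}
      - {center_ppm: 8.27, relative_intensity: 1.0, linewidth_hz: 2.0}
      - {center_ppm: 8.53, relative_intensity: 1.0, linewidth_hz: 2.0}
  - name: formate
    base_log_concentration: 0.0
    reference_peak: 8.46
    peaks:
      - {center_ppm: 8.46, relative_intensity: 1.0, linewidth_hz: 2.0}
  - name: TSP
    base_log_concentration: 1.5
    reference_peak: 0.0
    peaks:
      - {center_ppm: 0.0, relative_intensity: 9.0, linewidth_hz: 1.6}
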