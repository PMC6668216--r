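# Radial segmentation interchange format (JSON)

One eye per file. Top level object:

| field               | type    | meaning                                     |
|---------------------|---------|---------------------------------------------|
| `subject_id`        | string  | subject identifier                          |
| `eye_id`            | string  | eye identifier, conventionally `OD` / `OS`  |
| `scans`             | array   | exactly 6 scan objects (below)              |
| `truncated_width_mm`| number  | optional; present iff the set is truncated  |

Each element of `scans`:

| field              | type            | meaning                                        |
|--------------------|-----------------|------------------------------------------------|
| `angle_deg`        | number          | one of 0, 30, 60, 90, 120, 150                 |
| `scale_x_um`       | number          | microns per pixel, lateral                     |
| `scale_z_um`       | number          | microns per pixel, axial                       |
| `x_px`             | number[]        | strictly increasing lateral sample indices     |
| `ilm_z_px`         | number[]        | ILM depth per sample, pixels                   |
| `bm_z_px`          | (number|null)[] | BM depth per sample; `null` inside the opening |
| `margin_left_idx`  | integer         | 0-based index of the left BM opening margin    |
| `margin_right_idx` | 0-based index of the right margin (`> margin_left_idx`)  |

Conventions: all indices 0-based; depth `z` increases posteriorly; `bm_z_px`
must be non-null at the margins and at every sample outside them. Validation
errors are reported with a JSON-pointer path (e.g. `/scans/3/margin_left_idx`).
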