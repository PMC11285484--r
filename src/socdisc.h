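#ifndef SOCDISC_H
#define SOCDISC_H

// log first-passage-time density at the LOWER boundary of a Wiener diffusion
// with boundary separation a, drift v, relative start w (fraction of a above
// the lower boundary), unit diffusion coefficient; t is the decision time
// (observed rt minus the non-decision time). eps is the series truncation
// tolerance on the normalized-time density.
double wiener_lpdf_lower(double t, double a, double v, double w, double eps);

#endif
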