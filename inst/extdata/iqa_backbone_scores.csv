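network,dists,lpips,vsi,msssim,fsim,gmsd,nlpd,score
test_blur,0.723,0.638,0.868,0.472,0.679,0.783,0.546,0.673
resnet,0.848,0.740,0.961,0.817,0.891,0.847,0.673,0.825
inception,0.854,0.729,0.956,0.802,0.881,0.836,0.654,0.816
unet,0.853,0.740,0.959,0.812,0.885,0.843,0.665,0.822
ghostnet,0.881,0.724,0.960,0.810,0.889,0.837,0.655,0.822
mobilenet,0.884,0.729,0.961,0.809,0.891,0.838,0.654,0.824
agg,0.911,0.766,0.971,0.863,0.914,0.860,0.697,0.855
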