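hand,item_score,frequency,intensity,fi,peak
left,0,3.211,0.082,0.267,0.525
left,1,2.635,0.074,0.218,0.516
left,2,2.170,0.059,0.069,0.431
left,3,1.775,0.048,0.042,0.397
right,0,3.206,0.076,0.238,0.531
right,1,2.440,0.074,0.185,0.475
right,2,2.366,0.044,0.116,0.392
right,3,1.707,0.031,0.056,0.366
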