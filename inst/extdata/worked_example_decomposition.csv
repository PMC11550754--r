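kind,peer,lambda,bacillus,lactobacillus,lactococcus,streptococcus,fpd
raw,1,0.239,0.277,3.702,3.669,0.308,6.878
weighted,1,0.239,0.066,0.884,0.876,0.073,1.643
raw,2,0.273,0.277,0.616,0.067,0.820,6.357
weighted,2,0.273,0.076,0.168,0.018,0.224,1.737
raw,3,0.334,0.277,2.063,0.067,0.308,6.218
weighted,3,0.334,0.092,0.688,0.022,0.103,2.074
raw,4,0.088,1.739,3.269,0.067,0.308,7.529
weighted,4,0.088,0.153,0.287,0.006,0.027,0.661
raw,5,0.062,1.981,2.611,0.067,0.308,6.084
weighted,5,0.062,0.124,0.163,0.004,0.019,0.380
raw,6,0.041,1.038,2.747,0.067,0.308,7.017
weighted,6,0.041,0.004,0.011,0.000,0.001,0.029
own,,,0.277,0.616,0.067,0.308,3.509
sum_weighted,,,0.515,2.202,0.927,0.448,6.524
lack,,,0.238,1.586,0.860,0.140,3.015
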