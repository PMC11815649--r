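tag_name	region	offset	fraction
126	reporter	-2	9e-04
126	reporter	-1	0.0054
126	reporter	0	0.9739
126	reporter	1	0.0185
126	reporter	2	0.0013
126	complement	-2	7e-04
126	complement	-1	0.0046
126	complement	0	0.9769
126	complement	1	0.0165
126	complement	2	0.0013
127N	reporter	-2	5e-04
127N	reporter	-1	0.003
127N	reporter	0	0.9719
127N	reporter	1	0.023
127N	reporter	2	0.0016
127N	complement	-2	9e-04
127N	complement	-1	0.0062
127N	complement	0	0.9703
127N	complement	1	0.021
127N	complement	2	0.0016
127C	reporter	-2	7e-04
127C	reporter	-1	0.0046
127C	reporter	0	0.9758
127C	reporter	1	0.017
127C	reporter	2	0.0019
127C	complement	-2	5e-04
127C	complement	-1	0.0038
127C	complement	0	0.9788
127C	complement	1	0.015
127C	complement	2	0.0019
128N	reporter	-2	9e-04
128N	reporter	-1	0.0062
128N	reporter	0	0.9704
128N	reporter	1	0.0215
128N	reporter	2	0.001
128N	complement	-2	7e-04
128N	complement	-1	0.0054
128N	complement	0	0.9734
128N	complement	1	0.0195
128N	complement	2	0.001
128C	reporter	-2	5e-04
128C	reporter	-1	0.0038
128C	reporter	0	0.9789
128C	reporter	1	0.0155
128C	reporter	2	0.0013
128C	complement	-2	9e-04
128C	complement	-1	0.003
128C	complement	0	0.9813
128C	complement	1	0.0135
128C	complement	2	0.0013
129N	reporter	-2	7e-04
129N	reporter	-1	0.0054
129N	reporter	0	0.9723
129N	reporter	1	0.02
129N	reporter	2	0.0016
129N	complement	-2	5e-04
129N	complement	-1	0.0046
129N	complement	0	0.9753
129N	complement	1	0.018
129N	complement	2	0.0016
129C	reporter	-2	9e-04
129C	reporter	-1	0.003
129C	reporter	0	0.9802
129C	reporter	1	0.014
129C	reporter	2	0.0019
129C	complement	-2	7e-04
129C	complement	-1	0.0062
129C	complement	0	0.9792
129C	complement	1	0.012
129C	complement	2	0.0019
130N	reporter	-2	5e-04
130N	reporter	-1	0.0046
130N	reporter	0	0.9754
130N	reporter	1	0.0185
130N	reporter	2	0.001
130N	complement	-2	9e-04
130N	complement	-1	0.0038
130N	complement	0	0.9778
130N	complement	1	0.0165
130N	complement	2	0.001
130C	reporter	-2	7e-04
130C	reporter	-1	0.0062
130C	reporter	0	0.9688
130C	reporter	1	0.023
130C	reporter	2	0.0013
130C	complement	-2	5e-04
130C	complement	-1	0.0054
130C	complement	0	0.9718
130C	complement	1	0.021
130C	complement	2	0.0013
131N	reporter	-2	9e-04
131N	reporter	-1	0.0038
131N	reporter	0	0.9767
131N	reporter	1	0.017
131N	reporter	2	0.0016
131N	complement	-2	7e-04
131N	complement	-1	0.003
131N	complement	0	0.9797
131N	complement	1	0.015
131N	complement	2	0.0016
131C	reporter	-2	5e-04
131C	reporter	-1	0.0054
131C	reporter	0	0.9707
131C	reporter	1	0.0215
131C	reporter	2	0.0019
131C	complement	-2	9e-04
131C	complement	-1	0.0046
131C	complement	0	0.9731
131C	complement	1	0.0195
131C	complement	2	0.0019
132N	reporter	-2	7e-04
132N	reporter	-1	0.003
132N	reporter	0	0.9798
132N	reporter	1	0.0155
132N	reporter	2	0.001
132N	complement	-2	5e-04
132N	complement	-1	0.0062
132N	complement	0	0.9788
132N	complement	1	0.0135
132N	complement	2	0.001
132C	reporter	-2	9e-04
132C	reporter	-1	0.0046
132C	reporter	0	0.9732
132C	reporter	1	0.02
132C	reporter	2	0.0013
132C	complement	-2	7e-04
132C	complement	-1	0.0038
132C	complement	0	0.9762
132C	complement	1	0.018
132C	complement	2	0.0013
133N	reporter	-2	5e-04
133N	reporter	-1	0.0062
133N	reporter	0	0.9777
133N	reporter	1	0.014
133N	reporter	2	0.0016
133N	complement	-2	9e-04
133N	complement	-1	0.0054
133N	complement	0	0.9801
133N	complement	1	0.012
133N	complement	2	0.0016
133C	reporter	-2	7e-04
133C	reporter	-1	0.0038
133C	reporter	0	0.9751
133C	reporter	1	0.0185
133C	reporter	2	0.0019
133C	complement	-2	5e-04
133C	complement	-1	0.003
133C	complement	0	0.9781
133C	complement	1	0.0165
133C	complement	2	0.0019
134N	reporter	-2	9e-04
134N	reporter	-1	0.0054
134N	reporter	0	0.9697
134N	reporter	1	0.023
134N	reporter	2	0.001
134N	complement	-2	7e-04
134N	complement	-1	0.0046
134N	complement	0	0.9727
134N	complement	1	0.021
134N	complement	2	0.001
134C	reporter	-2	5e-04
134C	reporter	-1	0.003
134C	reporter	0	0.9782
134C	reporter	1	0.017
134C	reporter	2	0.0013
134C	complement	-2	9e-04
134C	complement	-1	0.0062
134C	complement	0	0.9766
134C	complement	1	0.015
134C	complement	2	0.0013
135N	reporter	-2	7e-04
135N	reporter	-1	0.0046
135N	reporter	0	0.9716
135N	reporter	1	0.0215
135N	reporter	2	0.0016
135N	complement	-2	5e-04
135N	complement	-1	0.0038
135N	complement	0	0.9746
135N	complement	1	0.0195
135N	complement	2	0.0016
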