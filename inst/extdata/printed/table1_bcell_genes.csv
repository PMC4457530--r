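category,gene,mean_normal_pb,mean_pure_b,ratio,p_value
surface_marker,CD268/BAFF-R,940.25,39402.54,41.9,0.001
surface_marker,CD83,3282.52,136406.91,41.6,0.033
surface_marker,CD79A,3447.71,119505.02,34.7,0.003
surface_marker,CD69,5409.08,181679.96,33.6,0.010
surface_marker,CD23/FCER2,226.31,7362.71,32.5,0.000
surface_marker,CD20,2112.32,66914.33,31.7,0.000
surface_marker,CD22,824.90,23927.76,29.0,0.002
surface_marker,CD19,607.52,17177.12,28.3,0.003
surface_marker,CD40/TNFRSF5,541.65,12031.25,22.2,0.000
surface_marker,CD200,142.54,3101.54,21.8,0.002
surface_marker,CD79B,181.90,3672.57,20.2,0.039
surface_marker,CD267/TACI,167.24,2259.35,13.5,0.004
surface_marker,CD180,443.95,3135.11,7.1,0.000
surface_marker,CD70,67.95,476.84,7.0,0.007
surface_marker,CD32/FCGR2B,1652.00,6086.44,3.7,0.023
surface_marker,CD81,4430.14,16162.38,3.6,0.007
surface_marker,CD124/IL4R,4546.82,14900.94,3.3,0.000
surface_marker,CD24,919.00,2537.83,2.8,0.013
surface_marker,CD150,288.06,788.85,2.7,0.009
surface_marker,CD71/TFRC,2572.30,6537.91,2.5,0.030
surface_marker,CD74,51335.01,121141.05,2.4,0.000
surface_marker,CD38,496.21,1108.49,2.2,0.048
transcription_factor,SOX11,1.48,128.09,86.7,0.011
transcription_factor,PAX5,267.77,10912.48,40.8,0.000
transcription_factor,EBF1,9.86,368.40,37.4,0.021
transcription_factor,IRF4,1106.86,7649.87,6.9,0.024
transcription_factor,JUN,6269.40,28921.65,4.6,0.000
transcription_factor,BCL2,1728.64,7690.48,4.4,0.003
transcription_factor,MYC,1640.93,5322.69,3.2,0.000
immunoglobulin,IGHD,1071.88,23185.99,21.6,0.000
immunoglobulin,IGHM,10313.33,198106.21,19.2,0.003
immunoglobulin,kappa,11354.34,70720.31,6.2,0.000
immunoglobulin,lambda,17487.73,64435.64,3.7,0.002
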