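feature,value
FO_Energy,1723.58160198
FO_TotalEnergy,16546.383379
FO_Entropy,5.04867007836
FO_Minimum,0.651820173581
FO_Percentile10,1.00249456864
FO_Percentile90,1.86865483815
FO_Maximum,2.5289880066
FO_Mean,1.40465893128
FO_Median,1.3553884826
FO_InterquartileRange,0.466075339179
FO_Range,1.87716783302
FO_MeanAbsoluteDeviation,0.275247149989
FO_RobustMeanAbsoluteDeviation,0.191141361534
FO_RootMeanSquared,1.4462797949
FO_Skewness,0.590839565181
FO_Kurtosis,3.05372190365
FO_Variance,0.118658531888
FO_Uniformity,0.0351558817985
SH_MeshVolume,7782.4
SH_VoxelVolume,7910.4
SH_SurfaceArea,2141.24002268
SH_SurfaceVolumeRatio,0.275138777585
SH_Sphericity,0.886940469502
SH_Maximum3DDiameter,32.6459798444
SH_Maximum2DDiameterSlice,32.5576411922
SH_Maximum2DDiameterColumn,32.0898737922
SH_Maximum2DDiameterRow,25.0567356214
SH_MajorAxisLength,28.0835414022
SH_MinorAxisLength,21.4524821756
SH_LeastAxisLength,17.9521599982
SH_Elongation,0.763880946079
SH_Flatness,0.639241317223
GLCM_Autocorrelation,492.594112056
GLCM_ClusterProminence,155858.208064
GLCM_ClusterShade,2152.65689056
GLCM_ClusterTendency,230.063983
GLCM_Contrast,61.8021000822
GLCM_Correlation,0.577673859702
GLCM_DifferenceAverage,6.31796308023
GLCM_DifferenceEntropy,4.00176319107
GLCM_DifferenceVariance,21.0332693289
GLCM_Id,0.23344290118
GLCM_Idm,0.141589016166
GLCM_Idmn,0.972912510301
GLCM_Idn,0.885891548296
GLCM_Imc1,-0.205475136543
GLCM_Imc2,0.934536420795
GLCM_InverseVariance,0.149910279961
GLCM_JointAverage,21.2234147505
GLCM_JointEnergy,0.00224121682214
GLCM_JointEntropy,9.07707280676
GLCM_MCC,0.65378441942
GLCM_MaximumProbability,0.00673477274753
GLCM_SumAverage,42.446829501
GLCM_SumEntropy,5.79868469273
GLCM_SumSquares,72.9665207706
GLRLM_GrayLevelNonUniformity,27.698279488
GLRLM_GrayLevelNonUniformityNormalized,0.0349789656232
GLRLM_GrayLevelVariance,74.6263549449
GLRLM_HighGrayLevelRunEmphasis,457.979382639
GLRLM_LongRunEmphasis,1.12708354803
GLRLM_LongRunHighGrayLevelEmphasis,517.839430618
GLRLM_LongRunLowGrayLevelEmphasis,0.00872849229348
GLRLM_LowGrayLevelRunEmphasis,0.00825013841675
GLRLM_RunEntropy,5.255911941
GLRLM_RunLengthNonUniformity,733.293334372
GLRLM_RunLengthNonUniformityNormalized,0.925869234411
GLRLM_RunPercentage,0.960978342046
GLRLM_RunVariance,0.0438490394899
GLRLM_ShortRunEmphasis,0.97080048187
GLRLM_ShortRunHighGrayLevelEmphasis,443.992288143
GLRLM_ShortRunLowGrayLevelEmphasis,0.00813925466003
GLSZM_GrayLevelNonUniformity,15.2887931034
GLSZM_GrayLevelNonUniformityNormalized,0.0329499851367
GLSZM_GrayLevelVariance,84.9524189952
GLSZM_HighGrayLevelZoneEmphasis,446.443965517
GLSZM_LargeAreaEmphasis,5.12068965517
GLSZM_LargeAreaHighGrayLevelEmphasis,2402.60775862
GLSZM_LargeAreaLowGrayLevelEmphasis,0.0259124029474
GLSZM_LowGrayLevelZoneEmphasis,0.0113138124841
GLSZM_SizeZoneNonUniformity,204.969827586
GLSZM_SizeZoneNonUniformityNormalized,0.441745318074
GLSZM_SmallAreaEmphasis,0.689711355966
GLSZM_SmallAreaHighGrayLevelEmphasis,302.163660876
GLSZM_SmallAreaLowGrayLevelEmphasis,0.00993411789921
GLSZM_ZoneEntropy,6.46504137965
GLSZM_ZonePercentage,0.563106796117
GLSZM_ZoneVariance,1.96700356718
NGTDM_Busyness,0.123591635048
NGTDM_Coarseness,0.0108519940511
NGTDM_Complexity,3263.04834114
NGTDM_Contrast,0.271309446222
NGTDM_Strength,7.93523689446
GLDM_DependenceEntropy,6.67836283301
GLDM_DependenceNonUniformity,254.786407767
GLDM_DependenceNonUniformityNormalized,0.309206805542
GLDM_DependenceVariance,0.985224809124
GLDM_GrayLevelNonUniformity,28.9684466019
GLDM_GrayLevelVariance,73.928733858
GLDM_HighGrayLevelEmphasis,458.640776699
GLDM_LargeDependenceEmphasis,5.04368932039
GLDM_LargeDependenceHighGrayLevelEmphasis,2385.14320388
GLDM_LargeDependenceLowGrayLevelEmphasis,0.022696094479
GLDM_LowGrayLevelEmphasis,0.00807512858474
GLDM_SmallDependenceEmphasis,0.473887877562
GLDM_SmallDependenceHighGrayLevelEmphasis,210.551767799
GLDM_SmallDependenceLowGrayLevelEmphasis,0.00594964696811
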