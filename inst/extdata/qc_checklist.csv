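item_id,section,kind,fields,label
ie1,intensity_essential,fields,light_source;power_mw;excitation_nm;emission_nm;objective;detector;detector_gain;pixel_size_um;dwell_time_us,"Consistent acquisition settings reported (source, power, wavelengths, objective, detector and gain, pixel size, dwell time or frame rate)"
ie2,intensity_essential,flag,normalized_by_power,"NAD(P)H and FAD signals normalized by incident power and other variable instrument settings"
ie3,intensity_essential,attest,controls_same_day_reported,"Same-day control-group measurements acquired and reported alongside the group of interest"
ie4,intensity_essential,convention,convention,"A normalized redox ratio form bounded in [0,1] adopted"
ie5,intensity_essential,attest,orr_definition_stated_in_text,"Adopted ORR definition and its metabolic directionality stated in the text, acknowledging alternative definitions"
ie6,intensity_essential,convention,convention,"Adopted ORR definition stamped prominently on figures and captions"
ie7,intensity_essential,attest,other_fluorophores_considered,"Potential impact of fluorophores and features beyond mitochondria/cytosol acknowledged"
ib1,intensity_best,flag,solution_calibrated,"Channels normalized with NADH and FAD solution-standard images for cross-study comparison"
ib2,intensity_best,flag,segmentation_mask_provided,"Nuclear, lipid droplet and lipofuscin-rich/lysosomal regions segmented out (or their inclusion justified)"
ib3,intensity_best,attest,signal_origin_controls_performed,"Controls confirming measured autofluorescence changes originate from NAD(P)H and FAD"
ib4,intensity_best,snr,,"SNR or SBR values of the NAD(P)H and FAD images reported"
ib5,intensity_best,attest,orthogonal_validation_performed,"Orthogonal validation (respirometry, mass spectrometry, omics, metabolite assays) of observed ORR changes"
fe1,flim_essential,fields,light_source;power_mw;excitation_nm;detector;detector_gain;pixel_size_um;dwell_time_us;rep_rate_hz,"Consistent FLIM acquisition settings reported (source, power, wavelengths, detector and gain, pixel size, binning, dwell time)"
fe2,flim_essential,fields,irf_fwhm_s;calibration_standard;calibration_lifetime_s,"System calibration reported: IRF (with FWHM) and fluorescence lifetime standard, measured under matching settings"
fe3,flim_essential,photon_stats,,"Sufficient photon counts achieved; minimum and typical photons per analyzed decay reported"
fe4,flim_essential,analysis,min_photons;bin_size,"Analysis details reported: threshold, fit model or phasor harmonic, binning, filtering"
fe5,flim_essential,endpoint,free_tau_s,"Lifetime or phasor locations of the pure molecular species used for relative fractions reported"
fb1,flim_best,flag,fit_distributions_exported,"Fit parameters and their distributions, with chi-square distributions, reported for the image"
fb2,flim_best,flag,segmentation_mask_provided,"Nuclear, lipid droplet and lipofuscin-rich/lysosomal regions removed before reporting FLIM metrics (or justified)"
fb3,flim_best,attest,signal_origin_controls_performed,"Controls confirming measured lifetime changes originate from NAD(P)H and FAD"
fb4,flim_best,attest,orthogonal_validation_performed,"Orthogonal validation (respirometry, mass spectrometry, omics, metabolite assays) of observed FLIM changes"
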