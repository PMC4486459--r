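# Synthetic 18-type atomic contact energy table (kcal/mol per contact).
# Constructed potential: per-type transfer-free-energy-like parameters,
# pair energy = sum of the two type parameters. Hydrophobic burial is
# favorable (negative), polar/charged burial unfavorable (positive).
# Swappable: any symmetric table with this layout can be supplied to
# desolvation_energy(table_path=).
type	N_bb	N_pro	CA	C_bb	O_bb	C_aliph	C_arom	C_polar	C_charged_arm	O_carboxyl	O_amide	O_hydroxyl	N_amide	N_pos	N_arom	S_thiol	S_thioether	O_terminal
N_bb	0.20	0.15	-0.15	-0.05	0.30	-0.80	-0.60	-0.10	-0.35	0.95	0.55	0.50	0.55	0.95	0.40	-0.30	-0.55	0.70
N_pro	0.15	0.10	-0.20	-0.10	0.25	-0.85	-0.65	-0.15	-0.40	0.90	0.50	0.45	0.50	0.90	0.35	-0.35	-0.60	0.65
CA	-0.15	-0.20	-0.50	-0.40	-0.05	-1.15	-0.95	-0.45	-0.70	0.60	0.20	0.15	0.20	0.60	0.05	-0.65	-0.90	0.35
C_bb	-0.05	-0.10	-0.40	-0.30	0.05	-1.05	-0.85	-0.35	-0.60	0.70	0.30	0.25	0.30	0.70	0.15	-0.55	-0.80	0.45
O_bb	0.30	0.25	-0.05	0.05	0.40	-0.70	-0.50	0.00	-0.25	1.05	0.65	0.60	0.65	1.05	0.50	-0.20	-0.45	0.80
C_aliph	-0.80	-0.85	-1.15	-1.05	-0.70	-1.80	-1.60	-1.10	-1.35	-0.05	-0.45	-0.50	-0.45	-0.05	-0.60	-1.30	-1.55	-0.30
C_arom	-0.60	-0.65	-0.95	-0.85	-0.50	-1.60	-1.40	-0.90	-1.15	0.15	-0.25	-0.30	-0.25	0.15	-0.40	-1.10	-1.35	-0.10
C_polar	-0.10	-0.15	-0.45	-0.35	0.00	-1.10	-0.90	-0.40	-0.65	0.65	0.25	0.20	0.25	0.65	0.10	-0.60	-0.85	0.40
C_charged_arm	-0.35	-0.40	-0.70	-0.60	-0.25	-1.35	-1.15	-0.65	-0.90	0.40	0.00	-0.05	0.00	0.40	-0.15	-0.85	-1.10	0.15
O_carboxyl	0.95	0.90	0.60	0.70	1.05	-0.05	0.15	0.65	0.40	1.70	1.30	1.25	1.30	1.70	1.15	0.45	0.20	1.45
O_amide	0.55	0.50	0.20	0.30	0.65	-0.45	-0.25	0.25	0.00	1.30	0.90	0.85	0.90	1.30	0.75	0.05	-0.20	1.05
O_hydroxyl	0.50	0.45	0.15	0.25	0.60	-0.50	-0.30	0.20	-0.05	1.25	0.85	0.80	0.85	1.25	0.70	0.00	-0.25	1.00
N_amide	0.55	0.50	0.20	0.30	0.65	-0.45	-0.25	0.25	0.00	1.30	0.90	0.85	0.90	1.30	0.75	0.05	-0.20	1.05
N_pos	0.95	0.90	0.60	0.70	1.05	-0.05	0.15	0.65	0.40	1.70	1.30	1.25	1.30	1.70	1.15	0.45	0.20	1.45
N_arom	0.40	0.35	0.05	0.15	0.50	-0.60	-0.40	0.10	-0.15	1.15	0.75	0.70	0.75	1.15	0.60	-0.10	-0.35	0.90
S_thiol	-0.30	-0.35	-0.65	-0.55	-0.20	-1.30	-1.10	-0.60	-0.85	0.45	0.05	0.00	0.05	0.45	-0.10	-0.80	-1.05	0.20
S_thioether	-0.55	-0.60	-0.90	-0.80	-0.45	-1.55	-1.35	-0.85	-1.10	0.20	-0.20	-0.25	-0.20	0.20	-0.35	-1.05	-1.30	-0.05
O_terminal	0.70	0.65	0.35	0.45	0.80	-0.30	-0.10	0.40	0.15	1.45	1.05	1.00	1.05	1.45	0.90	0.20	-0.05	1.20
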