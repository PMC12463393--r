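cell_id	group	cell_type
C01	Y	Neuron
C02	Y	Neuron
C03	Y	Astro
C04	Y	Neuron
C05	Y	Neuron
C06	Y	Astro
C07	Y	Neuron
C08	Y	Neuron
C09	Y	Astro
C10	Y	Neuron
C11	Y	Neuron
C12	Y	Astro
C13	Y	Neuron
C14	Y	Neuron
C15	Y	Astro
C16	Y	Neuron
C17	Y	Neuron
C18	Y	Astro
C19	Y	Neuron
C20	Y	Neuron
C21	O	Astro
C22	O	Neuron
C23	O	Neuron
C24	O	Astro
C25	O	Neuron
C26	O	Neuron
C27	O	Astro
C28	O	Neuron
C29	O	Neuron
C30	O	Astro
C31	O	Neuron
C32	O	Neuron
C33	O	Astro
C34	O	Neuron
C35	O	Neuron
C36	O	Astro
C37	O	Neuron
C38	O	Neuron
C39	O	Astro
C40	O	Neuron
C41	O.T	Neuron
C42	O.T	Astro
C43	O.T	Neuron
C44	O.T	Neuron
C45	O.T	Astro
C46	O.T	Neuron
C47	O.T	Neuron
C48	O.T	Astro
C49	O.T	Neuron
C50	O.T	Neuron
C51	O.T	Astro
C52	O.T	Neuron
C53	O.T	Neuron
C54	O.T	Astro
C55	O.T	Neuron
C56	O.T	Neuron
C57	O.T	Astro
C58	O.T	Neuron
C59	O.T	Neuron
C60	O.T	Astro
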